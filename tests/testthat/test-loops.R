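# Donut-filter loop calling: local expecteds, planted-dot recovery,
# merging, and the loops-per-length summary.

loop_genome <- function(n = 500, bs = 2000) {
  genome_layout(stats::setNames(n * bs, "chrL"), telomere_margin = bs)
}

raw_cm <- function(M, bs = 2000) {
  contact_matrix(Matrix::Matrix(M, sparse = TRUE),
                 bin_table(loop_genome(nrow(M), bs), bs), norm = "raw")
}

test_that("local expecteds equal the pixel value on a homogeneous matrix", {
  n <- 80
  cm <- raw_cm(matrix(6, n, n))
  le <- local_expected(cm, rep(1, n), "chrL", 30, 60,
                       loop_caller_config())
  expect_equal(unname(le$observed), 6)
  expect_equal(unname(le$lambda), rep(6, 4), tolerance = 1e-9)
})

test_that("the peak box shields a planted spike from its own donut expected", {
  n <- 100
  M <- matrix(4, n, n)
  spike <- cbind(rep(39:41, 3), rep(69:71, each = 3))
  M[spike] <- 32; M[spike[, 2:1]] <- 32
  cm <- raw_cm(M)
  le <- local_expected(cm, rep(1, n), "chrL", 40, 70,
                       loop_caller_config())
  expect_equal(unname(le$observed), 32)
  # all of the 3x3 spike sits inside the p-box: expecteds stay at background
  expect_lt(max(abs(le$lambda - 4)), 0.2)
})

test_that("neighborhoods are clipped at the diagonal for near-diagonal pixels", {
  n <- 60
  cm <- raw_cm(matrix(5, n, n))
  # sep 10: every neighborhood loses cells to the diagonal but keeps some
  le <- local_expected(cm, rep(1, n), "chrL", 20, 30,
                       loop_caller_config())
  expect_true(all(is.finite(le$lambda)))
  expect_equal(unname(le$lambda), rep(5, 4), tolerance = 1e-6)
  # sep 4: the lower-left quadrant is fully swallowed by diagonal + p-box
  # and the pixel is flagged (NA) under that model
  le4 <- local_expected(cm, rep(1, n), "chrL", 20, 24,
                        loop_caller_config())
  expect_true(is.na(le4$lambda[["ll"]]))
  expect_true(is.finite(le4$lambda[["donut"]]))
})

planted_dot_matrix <- function(n, dots, background = 6, fold = 8,
                               seed = 1) {
  set.seed(seed)
  lam <- matrix(0, n, n)
  sep <- abs(outer(1:n, 1:n, "-"))
  lam[sep > 0] <- background
  for (k in seq_len(nrow(dots))) {
    i <- dots[k, 1]; j <- dots[k, 2]
    lam[(i - 1):(i + 1), (j - 1):(j + 1)] <- background * fold
  }
  lam[lower.tri(lam, diag = TRUE)] <- 0
  M <- matrix(0, n, n)
  M[upper.tri(M)] <- rpois(sum(upper.tri(M)), lam[upper.tri(lam)])
  M + t(M)
}

test_that("one planted dot far from the diagonal yields exactly one call", {
  n <- 300
  dots <- cbind(100, 160)
  M <- planted_dot_matrix(n, dots, seed = 4)
  cm <- raw_cm(M)
  calls <- call_loops(cm, rep(1, nrow(M)), loop_caller_config())
  expect_equal(nrow(calls), 1)
  expect_lte(abs(calls$start1 / 2000 + 1 - 100), 1)
  expect_lte(abs(calls$start2 / 2000 + 1 - 160), 1)
  expect_equal(calls$loop_length, (calls$start2 - calls$start1))
  expect_true(all(calls$q_donut <= 0.01))
})

test_that("two dots with centroids 8 kb apart merge under a 10 kb radius", {
  n <- 300
  dots <- rbind(c(80, 180), c(84, 180))   # 4 bins = 8 kb apart
  M <- planted_dot_matrix(n, dots, seed = 6)
  cm <- raw_cm(M)
  calls <- call_loops(cm, rep(1, n), loop_caller_config())
  expect_equal(nrow(calls), 1)
  # with merging disabled the two dots are distinct
  calls0 <- call_loops(cm, rep(1, n),
                       loop_caller_config(merge_dist = 2000))
  expect_equal(nrow(calls0), 2)
})

test_that("identical inputs give byte-identical BEDPE output", {
  n <- 250
  M <- planted_dot_matrix(n, rbind(c(60, 120), c(150, 200)), seed = 9)
  cm <- raw_cm(M)
  f1 <- tempfile(); f2 <- tempfile()
  write_bedpe(call_loops(cm, rep(1, n), loop_caller_config()), f1)
  write_bedpe(call_loops(cm, rep(1, n), loop_caller_config()), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("configuration invariants are enforced", {
  expect_error(loop_caller_config(peak_width = 7, donut_width = 3),
               "donut_width")
  expect_error(loop_caller_config(fdr = 0), "fdr")
  n <- 40
  cm <- raw_cm(matrix(5, n, n))
  expect_error(call_loops(cm, rep(1, n),
                          loop_caller_config(resolution = 5000)),
               "resolution")
})

test_that("loops-per-length matches a hand tally per Mb", {
  gl <- genome_layout(c(c1 = 6e6, c2 = 4e6), telomere_margin = 6e4)
  lengths <- c(5000, 12000, 18000, 22000, 22000, 30000, 41000, 55000,
               70000, 95000)
  calls <- structure(data.frame(chrom = "c1", start1 = 0, end1 = 2000,
                                start2 = lengths, end2 = lengths + 2000,
                                loop_length = lengths),
                     class = c("loop_calls", "data.frame"))
  lpl <- loops_per_length(calls, gl, breaks = seq(0, 1e5, by = 2e4))
  expect_equal(lpl$count, c(3, 3, 2, 1, 1))
  expect_equal(lpl$per_mb, c(3, 3, 2, 1, 1) / 10)

  empty <- call_loops(raw_cm(matrix(1, 60, 60)), rep(1, 60),
                      loop_caller_config())
  expect_equal(nrow(empty), 0)
  lpl0 <- loops_per_length(empty, gl)
  expect_true(all(lpl0$count == 0))
})

test_that("merging is idempotent on its own output", {
  calls <- data.frame(chrom = "c", i = c(10, 13, 40), j = c(50, 52, 90),
                      obs = c(30, 20, 25), l_donut = c(5, 5, 5))
  m1 <- meiohic:::merge_calls(calls, radius = 5)
  m2 <- meiohic:::merge_calls(m1, radius = 5)
  expect_equal(m1, m2, ignore_attr = TRUE)
  expect_equal(nrow(m1), 2)
})
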