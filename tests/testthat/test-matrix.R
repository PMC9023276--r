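# Contact matrix construction, balancing, and display transforms.

test_that("binning counts pairs into the right bin pairs", {
  gl <- genome_layout(c(chrI = 100000, chrII = 50000),
                      telomere_margin = 5000)
  bt <- bin_table(gl, 20000)
  # a single pair at chrI:0 and chrI:25000 lands in bins 1 and 2
  p1 <- data.frame(chrom1 = "chrI", pos1 = 0, strand1 = "+", mapq1 = 60,
                   chrom2 = "chrI", pos2 = 25000, strand2 = "-",
                   mapq2 = 60)
  cm <- bin_pairs(p1, bt)
  expect_equal(as.numeric(cm$mat[1, 2]), 1)
  expect_equal(as.numeric(cm$mat[2, 1]), 1)
  expect_equal(sum(cm$mat), 2)  # symmetric storage, one pair

  # ten hand-placed pairs against a hand tally
  pos <- list(c("chrI", 5, "chrI", 5), c("chrI", 5, "chrI", 19999),
              c("chrI", 30000, "chrI", 90000),
              c("chrI", 90000, "chrI", 30000),
              c("chrII", 0, "chrII", 49999),
              c("chrI", 0, "chrII", 0), c("chrI", 0, "chrII", 0),
              c("chrI", 60000, "chrI", 60001),
              c("chrII", 20000, "chrII", 20001),
              c("chrI", 45000, "chrII", 45000))
  p10 <- do.call(rbind, lapply(pos, function(v)
    data.frame(chrom1 = v[1], pos1 = as.numeric(v[2]), strand1 = "+",
               mapq1 = 60, chrom2 = v[3], pos2 = as.numeric(v[4]),
               strand2 = "-", mapq2 = 60)))
  cm10 <- bin_pairs(p10, bt)
  # hand tally (global bins: chrI 1-5, chrII 6-8)
  expect_equal(as.numeric(cm10$mat[1, 1]), 2)  # rows 1 and 2
  expect_equal(as.numeric(cm10$mat[2, 5]), 2)  # rows 3 and 4
  expect_equal(as.numeric(cm10$mat[6, 8]), 1)
  expect_equal(as.numeric(cm10$mat[1, 6]), 2)
  expect_equal(as.numeric(cm10$mat[4, 4]), 1)
  expect_equal(as.numeric(cm10$mat[7, 7]), 1)
  expect_equal(as.numeric(cm10$mat[3, 8]), 1)
  # diagonal counted once, off-diagonal mirrored
  expect_equal(sum(cm10$mat), 2 * 10 - sum(Matrix::diag(cm10$mat)))

  expect_error(bin_pairs(data.frame(chrom1 = "chrX", pos1 = 1,
                                    chrom2 = "chrI", pos2 = 1), bt),
               "absent")
})

test_that("ICE leaves an already balanced matrix unchanged up to a scalar", {
  M <- matrix(1, 12, 12)
  cm <- as_cm(M)
  out <- ice_balance(cm, n_iter = 30)
  ratio <- as.matrix(out$mat) / M
  expect_lt(diff(range(ratio)), 1e-12)
  expect_lt(diff(range(out$bias)), 1e-12)
  expect_equal(out$norm, "ICE")
})

test_that("ICE run to convergence undoes a known diagonal distortion", {
  # A: balanced symmetric positive matrix built by the oracle itself
  set.seed(3)
  base <- random_positive_counts(15, seed = 3)
  A <- sinkhorn_oracle(base)$M
  A <- (A + t(A)) / 2
  d <- runif(15, 0.3, 3)
  M <- diag(d) %*% A %*% diag(d)
  M <- (M + t(M)) / 2
  cm <- contact_matrix(Matrix::Matrix(M, sparse = TRUE),
                       one_chrom(15), norm = "raw", mask = rep(FALSE, 15))
  out <- ice_balance(cm, n_iter = 5000, tol = 1e-12)
  marg <- Matrix::rowSums(out$mat)
  expect_lt(max(abs(marg / mean(marg) - 1)), 1e-6)
  # balanced result equals the oracle's balanced matrix up to one scalar
  orc <- sinkhorn_oracle(M)$M
  ratio <- as.matrix(out$mat) / ((orc + t(orc)) / 2)
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-6)
})

test_that("default ICE iteration count is 30", {
  expect_identical(formals(ice_balance)$n_iter, 30)
})

test_that("KR weights are flat on an equal-rowsum matrix and undo D A D", {
  # circulant-like symmetric matrix with equal row sums
  M <- outer(1:10, 1:10, function(i, j) 3 + ((i + j) %% 5))
  M <- (M + t(M)) / 2
  expect_lt(diff(range(rowSums(M))), 1e-12)
  kr <- kr_balance(as_cm(M))
  expect_lt(diff(range(kr$bias)), 1e-8)

  set.seed(11)
  A <- sinkhorn_oracle(random_positive_counts(12, seed = 11))$M
  A <- (A + t(A)) / 2
  d <- runif(12, 0.5, 2)
  M2 <- diag(d) %*% A %*% diag(d)
  M2 <- (M2 + t(M2)) / 2
  cm <- contact_matrix(Matrix::Matrix(M2, sparse = TRUE), one_chrom(12),
                       norm = "raw", mask = rep(FALSE, 12))
  kr2 <- kr_balance(cm, tol = 1e-12)
  rs <- Matrix::rowSums(kr2$mat)
  expect_lt(max(abs(rs / mean(rs) - 1)), 1e-8)
})

test_that("KR and fully converged ICE solve the same fixed point", {
  set.seed(21)
  M <- matrix(runif(40 * 40, 0.2, 3), 40, 40)
  M <- round(10 * (M + t(M)))
  cm <- as_cm(M)
  ice <- ice_balance(cm, n_iter = 10000, tol = 1e-13)
  kr <- kr_balance(cm, tol = 1e-13)
  ratio <- as.matrix(ice$mat) / as.matrix(kr$mat)
  expect_lt(max(abs(ratio / mean(ratio) - 1)), 1e-3)
})

test_that("balancing preserves symmetry and rejects degenerate input", {
  set.seed(5)
  M <- random_positive_counts(10, seed = 5)
  for (f in list(function(x) ice_balance(x, 30), kr_balance)) {
    out <- f(as_cm(M))
    expect_true(Matrix::isSymmetric(out$mat))
  }
  zero <- contact_matrix(Matrix::Matrix(0, 4, 4, sparse = TRUE),
                         one_chrom(4), norm = "raw")
  expect_error(ice_balance(zero), "all-zero")
  expect_error(kr_balance(zero), "all-zero")
})

test_that("KR balances disconnected support per component with a warning", {
  M <- matrix(0, 6, 6)
  M[1:3, 1:3] <- 2; M[4:6, 4:6] <- 5
  cm <- as_cm(M)
  expect_warning(kr <- kr_balance(cm), "disconnected")
  rs <- Matrix::rowSums(kr$mat)
  expect_lt(max(abs(rs - 1)), 1e-8)
})

test_that("scaling raw counts rescales balanced output and leaves ranks fixed", {
  set.seed(9)
  M <- random_positive_counts(14, seed = 9)
  a <- ice_balance(as_cm(M), 50)
  b <- ice_balance(as_cm(3 * M), 50)
  ratio <- as.matrix(b$mat) / as.matrix(a$mat)
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-10)
  expect_identical(as.matrix(percent_rank_scale(a)$mat),
                   as.matrix(percent_rank_scale(b)$mat))
})

test_that("percent-rank display saturates the top 5 percent", {
  # all entries equal: a single display value
  u <- percent_rank_scale(as_cm(matrix(4, 6, 6), norm = "ICE"))
  expect_equal(length(unique(u$mat@x)), 1)

  # 100 distinct values: everything at or above the 95th percentile is 1
  set.seed(13)
  n <- 200
  vals <- sample(seq(1, 100, by = 1))
  M <- matrix(0, n, n)
  idx <- cbind(1:100, 101:200)
  M[idx] <- vals; M <- M + t(M)
  cm <- contact_matrix(Matrix::Matrix(M, sparse = TRUE), one_chrom(n),
                       norm = "ICE", mask = rep(FALSE, n))
  disp <- percent_rank_scale(cm)
  cutoff <- attr(disp, "saturation")
  expect_equal(cutoff, sorted_percentile_oracle(vals, 0.95))
  got <- as.matrix(disp$mat)[idx]
  expect_true(all(got[vals >= cutoff] == 1))
  # everything below the top-5% rank stays below saturation
  expect_true(all(got[rank(vals) / length(vals) < 0.95] < 1))

  # 20 known values: cutoff equals the sort-based oracle exactly
  v20 <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3, 5, 8, 9, 7, 9, 3, 2, 3, 8, 4)
  M20 <- matrix(0, 40, 40)
  i20 <- cbind(1:20, 21:40)
  M20[i20] <- v20; M20 <- M20 + t(M20)
  cm20 <- contact_matrix(Matrix::Matrix(M20, sparse = TRUE),
                         one_chrom(40), norm = "ICE",
                         mask = rep(FALSE, 40))
  expect_equal(attr(percent_rank_scale(cm20), "saturation"),
               sorted_percentile_oracle(v20, 0.95))
  expect_error(percent_rank_scale(as_cm(matrix(0, 3, 3), norm = "ICE")),
               "empty")
})

test_that("subtraction maps saturate at the 95th percentile of |difference|", {
  A <- matrix(c(4, 1, 0, 2,
                1, 5, 2, 0,
                0, 2, 6, 1,
                2, 0, 1, 7), 4, 4)
  B <- matrix(c(1, 2, 1, 0,
                2, 2, 0, 3,
                1, 0, 3, 2,
                0, 3, 2, 4), 4, 4)
  bt <- one_chrom(4)
  cmA <- contact_matrix(Matrix::Matrix(A, sparse = TRUE), bt,
                        norm = "ICE", mask = rep(FALSE, 4))
  cmB <- contact_matrix(Matrix::Matrix(B, sparse = TRUE), bt,
                        norm = "ICE", mask = rep(FALSE, 4))
  sm <- subtraction_map(cmA, cmB)
  D <- A - B
  up <- D[upper.tri(D, diag = TRUE)]
  expect_equal(sm$T, sorted_percentile_oracle(abs(up), 0.95))
  expect_equal(as.matrix(sm$delta), D)
  expect_true(all(abs(as.matrix(sm$display)) <= sm$T + 1e-12))

  # antisymmetry with identical saturation
  sm2 <- subtraction_map(cmB, cmA)
  expect_equal(as.matrix(sm2$delta), -as.matrix(sm$delta))
  expect_equal(sm2$T, sm$T)

  # identical inputs: all zero, T = 0
  sm0 <- subtraction_map(cmA, cmA)
  expect_equal(sm0$T, 0)
  expect_equal(Matrix::nnzero(sm0$delta), 0)

  # mismatched bin tables refuse to subtract
  cmC <- contact_matrix(Matrix::Matrix(A, sparse = TRUE),
                        one_chrom(4, binsize = 500), norm = "ICE")
  expect_error(subtraction_map(cmA, cmC), "bin tables differ")
})

test_that("matrices round-trip through bins BED + COO text", {
  set.seed(17)
  M <- random_positive_counts(8, seed = 17)
  M[2, ] <- 0; M[, 2] <- 0   # a masked bin
  cm <- as_cm(M)
  out <- ice_balance(cm, 30)
  pre <- tempfile()
  write_coo(out, pre)
  layout <- attr(cm$bins, "layout")
  back <- read_coo(pre, layout, norm = "ICE")
  expect_equal(as.matrix(back$mat), as.matrix(out$mat), tolerance = 1e-12)
  expect_equal(back$mask, out$mask)
  expect_equal(back$bias, out$bias, tolerance = 1e-12)
})
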