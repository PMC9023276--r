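# Anti-diagonal arm-alignment profile, alignment index, and clustering
# enrichment.

# uniform power-law decay matrix with an optional anti-diagonal band of
# `fold`-times enrichment out to `extent` bins from the telomere corner
decay_with_band <- function(n, extent = 0, fold = 1, alpha = 1,
                            band = 1) {
  s <- pmax(abs(outer(1:n, 1:n, "-")), 0.5)
  M <- s^(-alpha)
  if (extent > 0 && fold != 1) {
    ii <- matrix(1:n, n, n); jj <- t(ii)
    d <- (pmin(ii, jj) + (n + 1 - pmax(ii, jj))) / 2
    onband <- abs(ii + jj - (n + 1)) <= band & d <= extent
    M[onband] <- M[onband] * fold
  }
  M
}

cm_from_dense <- function(M, binsize = 20000) {
  n <- nrow(M)
  gl <- genome_layout(stats::setNames(n * binsize, "chrT"),
                      telomere_margin = binsize)
  contact_matrix(Matrix::Matrix(M, sparse = TRUE),
                 bin_table(gl, binsize), norm = "ICE",
                 mask = rep(FALSE, n))
}

test_that("a homogeneous matrix yields a flat profile of ones", {
  cm <- cm_from_dense(matrix(2.5, 60, 60))
  pr <- antidiagonal_profile(cm, "chrT")
  expect_true(all(abs(pr$profile$score - 1) < 1e-9, na.rm = TRUE))
  # and stays flat under the expected-normalization whatever the scale
  pr7 <- antidiagonal_profile(cm_from_dense(matrix(7 * 2.5, 60, 60)),
                              "chrT")
  expect_equal(pr$profile$score, pr7$profile$score)
})

test_that("diagonal-only contacts give a zero far-corner profile", {
  n <- 60
  M <- matrix(0, n, n)
  M[abs(outer(1:n, 1:n, "-")) <= 1] <- 50
  pr <- antidiagonal_profile(cm_from_dense(M), "chrT")
  far <- pr$profile$score[pr$profile$d_bins <= 25]
  expect_true(all(far == 0, na.rm = TRUE))
  expect_true(any(!is.na(far)))
})

test_that("a planted 25-bin five-fold band is recovered as 0.5 Mb", {
  n <- 120
  M <- decay_with_band(n, extent = 25, fold = 5)
  pr <- antidiagonal_profile(cm_from_dense(M, 20000), "chrT")
  sc <- pr$profile$score
  plateau <- sc[pr$profile$d_bins >= 4 & pr$profile$d_bins <= 23]
  beyond <- sc[pr$profile$d_bins >= 28]
  expect_true(all(abs(plateau - 5) < 0.5, na.rm = TRUE))
  expect_true(all(abs(beyond - 1) < 0.3, na.rm = TRUE))
  # threshold halfway between baseline and plateau: 0.5 Mb +/- 1 bin
  ai <- alignment_index(pr, threshold = 3)
  expect_lt(abs(ai$index_mb - 0.5), 0.0201)
})

test_that("the index is zero when the profile never exceeds threshold", {
  M <- decay_with_band(80, extent = 0)
  pr <- antidiagonal_profile(cm_from_dense(M), "chrT")
  ai <- alignment_index(pr, threshold = 2)
  expect_equal(ai$index_mb, 0)
  expect_error(alignment_index(pr, threshold = -1), "> 0")
})

test_that("relabeling chromosome ends leaves the profile unchanged", {
  set.seed(31)
  n <- 80
  M <- decay_with_band(n, extent = 15, fold = 4)
  M <- M * exp(matrix(rnorm(n * n, sd = 0.05), n, n))
  M <- (M + t(M)) / 2
  pr <- antidiagonal_profile(cm_from_dense(M), "chrT")
  Mr <- M[n:1, n:1]   # reverse both ends
  prr <- antidiagonal_profile(cm_from_dense(Mr), "chrT")
  expect_equal(pr$profile$score, prr$profile$score, tolerance = 1e-10)
})

test_that("profiles need at least two bins and stop at the shorter arm", {
  gl <- genome_layout(c(chrS = 20000), telomere_margin = 5000)
  cm <- contact_matrix(Matrix::Matrix(1, 1, 1, sparse = TRUE),
                       bin_table(gl, 20000), norm = "ICE",
                       mask = FALSE)
  expect_error(antidiagonal_profile(cm, "chrS"), "2 bins")

  # off-center centromere: profile capped at the short arm
  n <- 100; bs <- 20000
  gl2 <- genome_layout(c(chrU = n * bs),
                       centromeres = data.frame(chrom = "chrU",
                                                start = 30 * bs,
                                                end = 31 * bs),
                       telomere_margin = bs)
  cmu <- contact_matrix(Matrix::Matrix(decay_with_band(n), sparse = TRUE),
                        bin_table(gl2, bs), norm = "ICE",
                        mask = rep(FALSE, n))
  pru <- antidiagonal_profile(cmu, "chrU")
  expect_equal(max(pru$profile$d_bins), 30)
})

test_that("alignment index recovers the planted extent from sampled maps", {
  gl <- sim_chromA()
  for (seed in 1:2) {
    cfg <- sim_config(layout = gl, binsize = 20000, align_extent = 1e6,
                      align_enrich = 3, loop_enrich = 0,
                      rabl_enrich = 0, telo_enrich = 0,
                      trans_fraction = 0, depth = 1e6, seed = seed)
    sim <- simulate_hic(cfg)
    cmi <- ice_balance(sim$matrix)
    ai <- alignment_index(antidiagonal_profile(cmi, "chrA"),
                          threshold = 2)
    expect_lt(abs(ai$index_mb - 1), 0.0201)
  }
})

test_that("cluster enrichment is 1 on homogeneous maps and recovers planted blocks", {
  gl <- genome_layout(c(chrA = 4e5, chrB = 4e5), telomere_margin = 4e4)
  bt <- bin_table(gl, 20000)
  nb <- nrow(bt)
  M <- matrix(1, nb, nb)
  cm <- contact_matrix(Matrix::Matrix(M, sparse = TRUE), bt,
                       norm = "ICE", mask = rep(FALSE, nb))
  ce <- cluster_enrichment(cm, telomere_regions(gl), telomere_regions(gl))
  expect_equal(ce$enrichment, 1, tolerance = 1e-12)

  # plant 5x telomere-telomere blocks on the uniform trans background
  tb <- region_bins(bt, telomere_regions(gl))
  chrom <- bt$chrom
  M5 <- M
  for (a in tb) for (b in tb)
    if (chrom[a] != chrom[b]) M5[a, b] <- 5
  cm5 <- contact_matrix(Matrix::Matrix(M5, sparse = TRUE), bt,
                        norm = "ICE", mask = rep(FALSE, nb))
  ce5 <- cluster_enrichment(cm5, telomere_regions(gl),
                            telomere_regions(gl))
  # background mean includes the planted blocks, pulling it above 1
  exact <- 5 / ce5$mean_background
  expect_equal(ce5$enrichment, exact, tolerance = 1e-12)
  expect_gt(ce5$enrichment, 4)
  expect_lt(ce5$enrichment, 5.01)

  expect_error(cluster_enrichment(cm, data.frame(chrom = "chrZ",
                                                 start = 0, end = 100),
                                  telomere_regions(gl)),
               "unknown")
})
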