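# Independent oracles used by the balancing and display tests. These are
# deliberately naive implementations, separate from the package code.

# Brute-force alternating marginal normalization (Sinkhorn-style) run to
# convergence; returns the scaled matrix and the accumulated row/column
# scalings. Works on plain dense matrices.
sinkhorn_oracle <- function(A, max_iter = 50000, tol = 1e-14) {
  M <- as.matrix(A)
  u <- rep(1, nrow(M))
  v <- rep(1, ncol(M))
  for (it in seq_len(max_iter)) {
    r <- rowSums(M)
    M <- M / r
    u <- u * r
    cs <- colSums(M)
    M <- sweep(M, 2, cs, "/")
    v <- v * cs
    if (max(abs(rowSums(M) - 1)) < tol && max(abs(colSums(M) - 1)) < tol)
      break
  }
  list(M = M, u = u, v = v, iterations = it)
}

# sort-based type-7 percentile, written out longhand (independent of
# stats::quantile)
sorted_percentile_oracle <- function(x, p) {
  xs <- sort(x)
  h <- (length(xs) - 1) * p
  lo <- floor(h)
  xs[lo + 1] + (h - lo) * (xs[min(lo + 2, length(xs))] - xs[lo + 1])
}

# one-chromosome layout/bin helper for matrix-level tests
one_chrom <- function(n_bins, binsize = 1000) {
  gl <- genome_layout(stats::setNames(n_bins * binsize, "chrT"),
                      telomere_margin = binsize)
  bin_table(gl, binsize)
}

# wrap a dense symmetric matrix as a contact_matrix on a 1-chromosome
# genome
as_cm <- function(M, norm = "raw", binsize = 1000) {
  bt <- one_chrom(nrow(M), binsize)
  contact_matrix(Matrix::Matrix(M, sparse = TRUE), bt, norm = norm)
}

# random symmetric strictly positive integer matrix
random_positive_counts <- function(n, seed) {
  set.seed(seed)
  A <- matrix(sample(1:50, n * n, replace = TRUE), n, n)
  A <- A + t(A)
  A
}

# greedy matching of loop calls to planted anchor pairs within a bin
# tolerance; returns precision/recall
match_calls <- function(calls, truth, binsize, tol_bins = 3) {
  if (is.null(truth) || !nrow(truth))
    return(list(precision = as.numeric(nrow(calls) == 0), recall = NA))
  if (!nrow(calls)) return(list(precision = NA, recall = 0))
  ci <- floor(calls$start1 / binsize) + 1
  cj <- floor(calls$start2 / binsize) + 1
  hit_truth <- rep(FALSE, nrow(truth))
  hit_call <- rep(FALSE, nrow(calls))
  for (k in seq_len(nrow(truth))) {
    d <- pmax(abs(ci - truth[k, 1]), abs(cj - truth[k, 2]))
    if (any(d <= tol_bins)) hit_truth[k] <- TRUE
  }
  for (m in seq_len(nrow(calls))) {
    d <- pmax(abs(ci[m] - truth[, 1]), abs(cj[m] - truth[, 2]))
    if (min(d) <= tol_bins) hit_call[m] <- TRUE
  }
  list(precision = mean(hit_call), recall = mean(hit_truth))
}

# single-chromosome genome used by simulation-heavy tests (arms of
# 2.08 Mb so planted alignment extents up to 2 Mb are admissible)
sim_chromA <- function(len = 4.2e6) {
  genome_layout(c(chrA = len),
                centromeres = data.frame(chrom = "chrA",
                                         start = len / 2 - 2e4,
                                         end = len / 2 + 2e4),
                telomere_margin = 6e4)
}
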