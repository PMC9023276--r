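#' Binned Hi-C contact matrix
#'
#' A symmetric sparse matrix of contact counts or normalized scores over a
#' [bin_table()], carrying a normalization tag (`raw`, `ICE`, `KR` or
#' `display`), a divisive per-bin bias vector (normalized value =
#' raw / (bias_i * bias_j); NA on masked bins) and a mask of bins removed
#' from balancing (zero raw coverage).
#'
#' @param mat symmetric (sparse) matrix of dimension `nrow(bins)`.
#' @param bins a [bin_table()].
#' @param norm normalization tag.
#' @param bias optional per-bin divisive bias vector.
#' @param mask optional logical vector of excluded bins; defaults to bins
#'   with zero marginal.
#' @return object of class `contact_matrix`.
#' @export
contact_matrix <- function(mat, bins, norm = "raw", bias = NULL,
                           mask = NULL) {
  stopifnot(inherits(bins, "bin_table"))
  n <- nrow(bins)
  mat <- methods::as(mat, "CsparseMatrix")
  if (nrow(mat) != n || ncol(mat) != n)
    stop("matrix dimension does not match bin table")
  if (!Matrix::isSymmetric(mat, tol = 0))
    mat <- Matrix::forceSymmetric(mat, uplo = "U")
  if (any(mat@x < 0)) stop("negative contact values")
  if (is.null(mask)) mask <- Matrix::rowSums(mat) == 0
  if (is.null(bias)) { bias <- rep(1, n); bias[mask] <- NA_real_ }
  structure(list(mat = mat, bins = bins, norm = norm,
                 bias = as.numeric(bias), mask = as.logical(mask)),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("<contact_matrix> ", nrow(x$bins), " bins @ ",
      binsize_of(x$bins), " bp, norm=", x$norm, ", ",
      format(Matrix::nnzero(x$mat), big.mark = ","), " nonzero, ",
      sum(x$mask), " masked bins\n", sep = "")
  invisible(x)
}

#' @export
dim.contact_matrix <- function(x) dim(x$mat)

#' Bin filtered read pairs into a raw contact matrix
#'
#' @param pairs data.frame of surviving pairs (0-based positions).
#' @param bins a [bin_table()]; an error is raised for pairs on
#'   chromosomes absent from it.
#' @return a raw [contact_matrix()].
#' @export
bin_pairs <- function(pairs, bins) {
  stopifnot(inherits(bins, "bin_table"))
  layout <- attr(bins, "layout")
  bad <- !(pairs$chrom1 %in% layout$chromosomes$name) |
    !(pairs$chrom2 %in% layout$chromosomes$name)
  if (any(bad)) stop("pair on chromosome absent from bin table")
  i <- bin_of(bins, pairs$chrom1, pairs$pos1)
  j <- bin_of(bins, pairs$chrom2, pairs$pos2)
  if (anyNA(i) || anyNA(j)) stop("pair position outside chromosome")
  lo <- pmin(i, j); hi <- pmax(i, j)
  n <- nrow(bins)
  m <- Matrix::sparseMatrix(i = lo, j = hi, x = 1, dims = c(n, n))
  m <- m + Matrix::t(m)
  Matrix::diag(m) <- Matrix::diag(m) / 2
  contact_matrix(m, bins, norm = "raw")
}

#' ICE balancing by iterative marginal correction
#'
#' The iterative-correction scheme: each round divides every entry by the
#' product of its row and column bias, where the bias is the bin marginal
#' rescaled to mean one over unmasked bins. The study runs 30 rounds; pass
#' `tol` to iterate to convergence of the marginal coefficient of
#' variation instead.
#'
#' @param cm a raw [contact_matrix()].
#' @param n_iter number of correction rounds (default 30).
#' @param tol optional early-stop tolerance on the CV of unmasked
#'   marginals.
#' @return a [contact_matrix()] tagged `ICE` with the accumulated divisive
#'   bias vector in `$bias`.
#' @export
ice_balance <- function(cm, n_iter = 30, tol = NULL) {
  stopifnot(inherits(cm, "contact_matrix"))
  if (cm$norm != "raw") stop("ice_balance expects a raw matrix")
  if (Matrix::nnzero(cm$mat) == 0) stop("all-zero matrix")
  m <- cm$mat
  keep <- !cm$mask
  bias <- rep(1, nrow(m))
  for (it in seq_len(n_iter)) {
    marg <- Matrix::rowSums(m)
    b <- marg / mean(marg[keep])
    b[!keep | b == 0] <- 1
    inv <- Matrix::Diagonal(x = 1 / b)
    m <- inv %*% m %*% inv
    bias <- bias * b
    if (!is.null(tol)) {
      marg <- Matrix::rowSums(m)[keep]
      if (stats::sd(marg) / mean(marg) < tol) break
    }
  }
  bias[!keep] <- NA_real_
  out <- contact_matrix(Matrix::forceSymmetric(m, "U"), cm$bins,
                        norm = "ICE", bias = bias, mask = cm$mask)
  out
}

# connected components of the support graph restricted to `keep` bins
support_components <- function(m, keep) {
  n <- nrow(m)
  comp <- rep(NA_integer_, n)
  mt <- methods::as(m, "TsparseMatrix")
  adj <- split(mt@j[mt@x != 0] + 1L, mt@i[mt@x != 0] + 1L)
  cur <- 0L
  for (s in which(keep)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- adj[[as.character(v)]]
      nb <- nb[keep[nb] & is.na(comp[nb])]
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# Knight-Ruiz balancing core: returns x with diag(x) A diag(x) doubly
# stochastic. Inner-outer Newton iteration with CG, following the
# published algorithm.
kr_core <- function(A, tol = 1e-10, max_mvp = 50000) {
  n <- nrow(A)
  e <- rep(1, n)
  x <- e
  delta <- 0.1; Delta <- 3
  g <- 0.9; etamax <- 0.1
  eta <- etamax
  rt <- tol^2
  v <- x * as.vector(A %*% x)
  rk <- 1 - v
  rho_km1 <- sum(rk * rk)
  rout <- rho_km1; rold <- rout
  mvp <- 0
  while (rout > rt) {
    k <- 0
    y <- e
    innertol <- max(eta^2 * rout, rt)
    while (rho_km1 > innertol) {
      k <- k + 1
      if (k == 1) { Z <- rk / v; p <- Z; rho_km1 <- sum(rk * Z) }
      w <- x * as.vector(A %*% (x * p)) + v * p
      alpha <- rho_km1 / sum(p * w)
      ap <- alpha * p
      ynew <- y + ap
      if (min(ynew) <= delta) {
        if (delta == 0) break
        ind <- ap < 0
        gamma <- min((delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      if (max(ynew) >= Delta) {
        ind <- ynew > Delta
        gamma <- min((Delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      y <- ynew
      rk <- rk - alpha * w
      rho_km2 <- rho_km1
      Z <- rk / v
      rho_km1 <- sum(rk * Z)
      p <- Z + (rho_km1 / rho_km2) * p
      mvp <- mvp + 1
      if (mvp > max_mvp) stop("KR balancing did not converge")
    }
    x <- x * y
    v <- x * as.vector(A %*% x)
    rk <- 1 - v
    rho_km1 <- sum(rk * rk)
    rout <- rho_km1
    mvp <- mvp + 1
    if (mvp > max_mvp) stop("KR balancing did not converge")
    rat <- rout / rold; rold <- rout
    eta_o <- eta
    eta <- g * rat
    if (g * eta_o^2 > 0.1) eta <- max(eta, g * eta_o^2)
    eta <- max(min(eta, etamax), 0.5 * tol / sqrt(rout))
  }
  x
}

#' Knight-Ruiz matrix balancing
#'
#' Computes weights `w` such that `diag(w) M diag(w)` has equal row sums
#' (doubly stochastic on the unmasked support) via the Knight-Ruiz
#' inner-outer Newton iteration. Disconnected support is balanced per
#' connected component with a warning; the stored bias is divisive
#' (`1/w`), matching the ICE convention.
#'
#' @param cm a raw [contact_matrix()].
#' @param tol convergence tolerance on the residual of the balanced
#'   marginals.
#' @return a [contact_matrix()] tagged `KR`.
#' @export
kr_balance <- function(cm, tol = 1e-10) {
  stopifnot(inherits(cm, "contact_matrix"))
  if (cm$norm != "raw") stop("kr_balance expects a raw matrix")
  if (Matrix::nnzero(cm$mat) == 0) stop("all-zero matrix")
  keep <- !cm$mask
  comp <- support_components(cm$mat, keep)
  ncomp <- max(comp, na.rm = TRUE)
  if (ncomp > 1)
    warning("disconnected contact support: balancing ", ncomp,
            " components independently")
  w <- rep(NA_real_, nrow(cm$mat))
  for (k in seq_len(ncomp)) {
    idx <- which(!is.na(comp) & comp == k)
    if (length(idx) == 1) {
      d <- cm$mat[idx, idx]
      w[idx] <- if (d > 0) 1 / sqrt(d) else NA_real_
      next
    }
    A <- cm$mat[idx, idx, drop = FALSE]
    sc <- mean(Matrix::rowSums(A))   # pre-scale for numerical headroom
    w[idx] <- kr_core(A / sc, tol = tol) / sqrt(sc)
  }
  bias <- 1 / w
  binv <- ifelse(is.na(w), 0, w)
  D <- Matrix::Diagonal(x = binv)
  m <- Matrix::forceSymmetric(D %*% cm$mat %*% D, "U")
  contact_matrix(m, cm$bins, norm = "KR", bias = bias,
                 mask = cm$mask | is.na(w))
}

# type-7 quantile: linear interpolation between order statistics
q95 <- function(x) stats::quantile(x, 0.95, type = 7, names = FALSE)

#' Percent-rank display transform with top-5% saturation
#'
#' Maps every nonzero normalized score to its percentile rank; all scores
#' at or above the 95th percentile saturate at the maximum intensity 1.0,
#' matching heatmaps whose maximum corresponds to the top 5% score.
#'
#' @param cm a normalized [contact_matrix()].
#' @return a [contact_matrix()] tagged `display` with values in \[0, 1\]
#'   and attribute `saturation` (the 95th-percentile cutoff on the input
#'   scale).
#' @export
percent_rank_scale <- function(cm) {
  stopifnot(inherits(cm, "contact_matrix"))
  m <- methods::as(methods::as(cm$mat, "generalMatrix"), "TsparseMatrix")
  up <- m@i <= m@j & m@x != 0
  x <- m@x[up]
  if (!length(x)) stop("empty matrix")
  cutoff <- q95(x)
  r <- rank(x, ties.method = "average") / length(x)
  disp <- pmin(r / 0.95, 1)
  disp[x >= cutoff] <- 1
  out <- Matrix::sparseMatrix(i = m@i[up] + 1L, j = m@j[up] + 1L,
                              x = disp, dims = dim(m), symmetric = TRUE)
  res <- contact_matrix(out, cm$bins, norm = "display", bias = cm$bias,
                        mask = cm$mask)
  attr(res, "saturation") <- cutoff
  res
}

#' Subtraction heatmap between two normalized matrices
#'
#' Elementwise difference `A - B` on the union of supports; the saturation
#' value `T` is the 95th percentile of the absolute differences over
#' unmasked entries, and the display matrix is clipped to `[-T, +T]`
#' (drawn as minimum/maximum intensity). Antisymmetric in its arguments.
#'
#' @param a,b [contact_matrix()] objects on the same bin table with the
#'   same normalization tag.
#' @return object of class `subtraction_map` with elements `delta`
#'   (sparse difference), `T` (saturation), `display` (clipped), `bins`.
#' @export
subtraction_map <- function(a, b) {
  stopifnot(inherits(a, "contact_matrix"), inherits(b, "contact_matrix"))
  if (!identical(dim(a$mat), dim(b$mat)) ||
      !identical(a$bins$chrom, b$bins$chrom) ||
      !identical(binsize_of(a$bins), binsize_of(b$bins)))
    stop("bin tables differ")
  if (!identical(a$norm, b$norm)) stop("normalization tags differ")
  d <- a$mat - b$mat
  mask <- a$mask | b$mask
  # evaluate T on the union of supports: cells where either input has a
  # stored entry, including exact cancellations (difference zero)
  supp <- function(m) {
    t <- methods::as(methods::as(m, "generalMatrix"), "TsparseMatrix")
    unique(cbind(t@i + 1L, t@j + 1L)[t@i <= t@j, , drop = FALSE])
  }
  un <- unique(rbind(supp(a$mat), supp(b$mat)))
  un <- un[!mask[un[, 1]] & !mask[un[, 2]], , drop = FALSE]
  vals <- abs(d[un])
  Tsat <- if (length(vals)) q95(vals) else 0
  disp <- pmax(pmin(d, Tsat), -Tsat)
  structure(list(delta = d, T = Tsat, display = disp, bins = a$bins,
                 norm = a$norm),
            class = "subtraction_map")
}

#' @export
print.subtraction_map <- function(x, ...) {
  cat("<subtraction_map> ", nrow(x$bins), " bins, saturation T = ",
      signif(x$T, 6), "\n", sep = "")
  invisible(x)
}

#' Extract the dense intra-chromosomal block of one chromosome
#'
#' @param cm a [contact_matrix()].
#' @param chrom chromosome name.
#' @return list with dense `mat`, logical `mask`, `binsize`, global bin
#'   `offset` and chromosome name.
#' @export
cis_block <- function(cm, chrom) {
  rg <- chrom_bin_range(cm$bins, chrom)
  idx <- rg[1]:rg[2]
  list(mat = as.matrix(cm$mat[idx, idx, drop = FALSE]),
       mask = cm$mask[idx], bias = cm$bias[idx],
       binsize = binsize_of(cm$bins), offset = rg[1] - 1L, chrom = chrom)
}

#' Write / read a contact matrix as bins BED + COO triples
#'
#' Bins as BED with a fourth bin-id column; values as
#' `bin1<TAB>bin2<TAB>value` (upper triangle, 1-based ids); bias weights
#' as two-column text.
#'
#' @param cm a [contact_matrix()].
#' @param prefix path prefix; writes `<prefix>.bins.bed`, `<prefix>.coo`,
#'   `<prefix>.weights`.
#' @return the prefix, invisibly.
#' @export
write_coo <- function(cm, prefix) {
  b <- cm$bins
  utils::write.table(data.frame(b$chrom, b$start, b$end, b$bin),
                     paste0(prefix, ".bins.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  m <- methods::as(methods::as(cm$mat, "generalMatrix"), "TsparseMatrix")
  up <- m@i <= m@j
  ord <- order(m@i[up], m@j[up])
  df <- data.frame(m@i[up][ord] + 1L, m@j[up][ord] + 1L,
                   format(m@x[up][ord], digits = 15, trim = TRUE))
  utils::write.table(df, paste0(prefix, ".coo"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  w <- ifelse(is.na(cm$bias), "NA",
              format(cm$bias, digits = 15, trim = TRUE))
  utils::write.table(data.frame(b$bin, w), paste0(prefix, ".weights"),
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' @rdname write_coo
#' @param layout a [genome_layout()] used to rebuild the bin table.
#' @param norm normalization tag of the stored values.
#' @export
read_coo <- function(prefix, layout, norm = "raw") {
  bed <- utils::read.table(paste0(prefix, ".bins.bed"), sep = "\t",
                           stringsAsFactors = FALSE)
  bs <- max(bed[[3]] - bed[[2]])
  bins <- bin_table(layout, bs)
  if (nrow(bins) != nrow(bed)) stop("bin table does not match layout")
  coo <- utils::read.table(paste0(prefix, ".coo"), sep = "\t")
  m <- Matrix::sparseMatrix(i = coo[[1]], j = coo[[2]], x = coo[[3]],
                            dims = c(nrow(bins), nrow(bins)),
                            symmetric = TRUE)
  bias <- NULL
  wfile <- paste0(prefix, ".weights")
  if (file.exists(wfile)) {
    w <- utils::read.table(wfile, sep = "\t", strip.white = TRUE,
                           na.strings = c("NA", "nan"))
    bias <- as.numeric(w[[2]][order(w[[1]])])
  }
  contact_matrix(m, bins, norm = norm, bias = bias,
                 mask = if (is.null(bias)) NULL else is.na(bias))
}
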