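# Bouquet architecture statistics: anti-diagonal arm-alignment profile,
# the alignment index, and centromere/telomere clustering enrichment.

# per-separation mean normalized contact for one cis block, with a band
# of half-width `exclude` bins around the anti-diagonal left out (the
# bouquet signal itself must not inflate its own expected), then
# lowess-smoothed in log-log space for stability at sparse separations.
distance_expected <- function(block, exclude = 0, smooth = TRUE) {
  m <- block$mat
  n <- nrow(m)
  keep <- !block$mask
  sums <- cnts <- numeric(n - 1)
  for (k in seq_len(n - 1)) {
    i <- seq_len(n - k)
    ok <- keep[i] & keep[i + k]
    if (exclude > 0) ok <- ok & abs(2 * i + k - (n + 1)) > exclude
    if (!any(ok)) next
    sums[k] <- sum(m[cbind(i[ok], i[ok] + k)])
    cnts[k] <- sum(ok)
  }
  e <- ifelse(cnts > 0, sums / cnts, NA_real_)
  if (smooth) {
    w <- which(!is.na(e) & e > 0)
    if (length(w) >= 10) {
      fit <- stats::lowess(log(w), log(e[w]), f = 0.3)
      e[w] <- exp(stats::approx(fit$x, fit$y, xout = log(w), rule = 2)$y)
    }
  }
  e
}

#' Anti-diagonal arm-alignment profile of one chromosome
#'
#' For each distance `d` (in bins) from the chromosome ends, averages the
#' expected-normalized contact between the bin `d` from the left telomere
#' and the bin `d` from the right telomere over a band of half-width
#' `band_halfwidth` bins around the exact anti-diagonal. Telomere-bundled
#' arms ("X-shaped" maps) give values well above 1 out to the extent of
#' arm alignment.
#'
#' @param cm an ICE-normalized [contact_matrix()] (20 kb resolution in the
#'   study).
#' @param chrom chromosome name.
#' @param band_halfwidth band half-width in bins around the anti-diagonal
#'   (default 1).
#' @param smooth_bins width of the centered moving average later applied
#'   by [alignment_index()] (stored on the profile; default 3).
#' @param expected_exclude half-width in bins of the anti-diagonal band
#'   excluded from the per-distance expected model.
#' @return object of class `antidiagonal_profile`: data.frame of `d_bins`,
#'   `d_bp`, `score` plus metadata.
#' @export
antidiagonal_profile <- function(cm, chrom, band_halfwidth = 1,
                                 smooth_bins = 3, expected_exclude = 2) {
  stopifnot(inherits(cm, "contact_matrix"))
  block <- cis_block(cm, chrom)
  n <- nrow(block$mat)
  if (n < 2) stop("chromosome shorter than 2 bins")
  e <- distance_expected(block, exclude = expected_exclude)
  layout <- attr(cm$bins, "layout")
  dmax <- floor(n / 2)
  if (!is.null(layout$centromeres)) {
    cen <- layout$centromeres[layout$centromeres$chrom == chrom, ]
    if (nrow(cen) == 1) {
      L <- chrom_length(layout, chrom)
      arm <- min(cen$start, L - cen$end)
      dmax <- min(dmax, ceiling(arm / block$binsize))
    }
  }
  keep <- !block$mask
  score <- rep(NA_real_, dmax)
  w <- band_halfwidth
  for (d in seq_len(dmax)) {
    j0 <- n + 1 - d
    # symmetric band: column offsets at row d plus row offsets at column
    # j0 (the union is invariant under relabeling the chromosome ends)
    px <- unique(rbind(cbind(d, j0 + (-w):w), cbind(d + (-w):w, j0)))
    px <- px[px[, 1] >= 1 & px[, 2] <= n & px[, 2] > px[, 1], ,
             drop = FALSE]
    if (!nrow(px)) next
    sep <- px[, 2] - px[, 1]
    usable <- keep[px[, 1]] & keep[px[, 2]]
    ok <- usable & !is.na(e[sep]) & e[sep] > 0
    if (any(ok)) {
      score[d] <- mean(block$mat[px[ok, , drop = FALSE]] / e[sep[ok]])
    } else if (any(usable) &&
               all(block$mat[px[usable, , drop = FALSE]] == 0)) {
      # no expected model (empty separations) but no signal either
      score[d] <- 0
    }
  }
  structure(list(profile = data.frame(
    d_bins = seq_len(dmax),
    d_bp = (seq_len(dmax) - 0.5) * block$binsize,
    score = score),
    chrom = chrom, binsize = block$binsize,
    band_halfwidth = band_halfwidth, smooth_bins = smooth_bins),
    class = "antidiagonal_profile")
}

#' @export
print.antidiagonal_profile <- function(x, ...) {
  cat("<antidiagonal_profile> ", x$chrom, ", ", nrow(x$profile),
      " distances @ ", x$binsize, " bp, band +/-", x$band_halfwidth,
      " bins\n", sep = "")
  invisible(x)
}

# centered moving average, NA-tolerant
moving_average <- function(x, w) {
  if (w <= 1) return(x)
  h <- floor(w / 2)
  n <- length(x)
  vapply(seq_len(n), function(i) {
    v <- x[max(1, i - h):min(n, i + h)]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
}

#' Alignment index: telomere-proximal extent of arm alignment
#'
#' The shortest distance from the telomere at which the smoothed
#' anti-diagonal profile first drops below the threshold - equivalently
#' the largest `d*` such that the smoothed score stays at or above the
#' threshold for all evaluable `d <= d*`. Reported in Mb. A profile below
#' threshold at the first evaluable distance gives index 0; a profile
#' that never drops gives the full profile extent.
#'
#' @param profile an [antidiagonal_profile()].
#' @param threshold positive threshold on the expected-normalized scale
#'   (default 2.0, configurable to match a chosen reference).
#' @return object of class `alignment_index_result` with `index_mb`,
#'   `threshold`, `chrom`, the smoothed profile and the crossing rule tag.
#' @export
alignment_index <- function(profile, threshold = 2.0) {
  stopifnot(inherits(profile, "antidiagonal_profile"))
  if (threshold <= 0) stop("threshold must be > 0")
  sm <- moving_average(profile$profile$score, profile$smooth_bins)
  # the first distances sit in the telomere corner where the expected
  # model rests on almost no background pixels; the crossing rule starts
  # at the first d with a complete centered smoothing window
  h <- floor(profile$smooth_bins / 2)
  evaluable <- which(!is.na(sm))
  evaluable <- evaluable[evaluable > h]
  if (!length(evaluable)) stop("profile has no evaluable distances")
  below <- evaluable[sm[evaluable] < threshold]
  d_star <- if (!length(below)) {
    max(evaluable)
  } else if (below[1] == evaluable[1]) {
    0L
  } else {
    # last evaluable d before the first downward crossing
    max(evaluable[evaluable < below[1]])
  }
  structure(list(index_mb = d_star * profile$binsize / 1e6,
                 d_star_bins = d_star, threshold = threshold,
                 chrom = profile$chrom,
                 crossing_rule = "first_downward_crossing_of_smoothed",
                 smoothed = sm, profile = profile),
            class = "alignment_index_result")
}

#' @export
print.alignment_index_result <- function(x, ...) {
  cat("<alignment_index> ", x$chrom, ": ", signif(x$index_mb, 4),
      " Mb (threshold ", x$threshold, "x expected)\n", sep = "")
  invisible(x)
}

#' Inter-chromosomal clustering enrichment between two region sets
#'
#' Mean normalized contact between bins of regions A and bins of regions B
#' on different chromosomes, divided by the mean over all unmasked trans
#' bin pairs. Equals 1 on a homogeneous matrix; telomere-telomere
#' enrichment quantifies bouquet clustering, centromere-centromere the
#' Rabl orientation.
#'
#' @param cm a normalized [contact_matrix()].
#' @param regionsA,regionsB data.frames with `chrom`, `start`, `end`.
#' @return object of class `cluster_enrichment` with `enrichment`,
#'   `mean_region`, `mean_background` and pair counts.
#' @export
cluster_enrichment <- function(cm, regionsA, regionsB) {
  stopifnot(inherits(cm, "contact_matrix"))
  binsA <- region_bins(cm$bins, regionsA)
  binsB <- region_bins(cm$bins, regionsB)
  binsA <- binsA[!cm$mask[binsA]]
  binsB <- binsB[!cm$mask[binsB]]
  chrom <- cm$bins$chrom
  pr <- expand.grid(a = binsA, b = binsB)
  pr <- pr[chrom[pr$a] != chrom[pr$b], ]
  if (!nrow(pr)) stop("no trans region pairs")
  mean_region <- mean(cm$mat[cbind(pr$a, pr$b)])
  # background: all unmasked trans pairs (zeros included)
  keep <- which(!cm$mask)
  tab <- table(chrom[keep])
  n_trans <- (sum(tab)^2 - sum(tab^2))   # ordered trans pairs
  mt <- methods::as(methods::as(cm$mat, "generalMatrix"), "TsparseMatrix")
  ok <- !cm$mask[mt@i + 1L] & !cm$mask[mt@j + 1L] &
    chrom[mt@i + 1L] != chrom[mt@j + 1L]
  mean_bg <- sum(mt@x[ok]) / n_trans
  structure(list(enrichment = mean_region / mean_bg,
                 mean_region = mean_region, mean_background = mean_bg,
                 n_region_pairs = nrow(pr), n_background_pairs = n_trans),
            class = "cluster_enrichment")
}

#' @export
print.cluster_enrichment <- function(x, ...) {
  cat("<cluster_enrichment> ", signif(x$enrichment, 4), " (",
      x$n_region_pairs, " region pairs vs trans background)\n", sep = "")
  invisible(x)
}
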