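# Contact probability P(s): distance-decay curves, Loess smoothing in
# log-log space, derivatives and shoulder (transition point) detection.

#' Construct a P(s) curve from precomputed values
#'
#' Mostly used internally by [compute_ps()]; exported so analytic or
#' constructed curves can be pushed through the smoothing and transition
#' machinery.
#'
#' @param s distance-bin centers in bp, strictly increasing.
#' @param P mean contact per distance bin (>= 0).
#' @param npairs optional pair counts per bin (0 flags empty bins).
#' @param normalized whether the curve was area-normalized.
#' @return object of class `ps_curve`.
#' @export
ps_curve <- function(s, P, npairs = NULL, normalized = FALSE) {
  if (is.unsorted(s, strictly = TRUE)) stop("distance bins must increase")
  if (any(P < 0)) stop("P(s) must be non-negative")
  if (is.null(npairs)) npairs <- rep(1, length(s))
  structure(list(table = data.frame(s = s, P = P, npairs = npairs),
                 normalized = normalized),
            class = "ps_curve")
}

#' @export
print.ps_curve <- function(x, ...) {
  cat("<ps_curve> ", nrow(x$table), " distance bins, s in [",
      format(min(x$table$s), big.mark = ","), ", ",
      format(max(x$table$s), big.mark = ","), "] bp\n", sep = "")
  invisible(x)
}

#' Contact frequency versus genomic distance, P(s)
#'
#' Pools all intra-chromosomal unmasked bin pairs of the matrix into
#' log-spaced distance bins: P = (sum of scores) / (number of evaluable
#' bin pairs) per bin, then area-normalized so that sum(P * ds) = 1,
#' making curves from different sequencing depths directly comparable.
#'
#' @param cm a normalized [contact_matrix()].
#' @param log_bins_per_decade number of log-spaced distance bins per
#'   decade (default 8).
#' @param s_min_bins smallest separation included, in bins (default 2;
#'   separations 0-1 bins are dominated by self-ligation remnants).
#' @param chroms chromosomes to pool (default all).
#' @return a [ps_curve()].
#' @export
compute_ps <- function(cm, log_bins_per_decade = 8, s_min_bins = 2,
                       chroms = NULL) {
  stopifnot(inherits(cm, "contact_matrix"))
  layout <- attr(cm$bins, "layout")
  if (is.null(chroms)) chroms <- layout$chromosomes$name
  bs <- binsize_of(cm$bins)
  # per-separation sums/counts pooled over chromosomes (bins align in bp)
  nmax <- max(table(cm$bins$chrom))
  sums <- cnts <- numeric(nmax - 1)
  any_cis <- FALSE
  for (ch in chroms) {
    block <- cis_block(cm, ch)
    n <- nrow(block$mat)
    keep <- !block$mask
    for (k in seq_len(n - 1)) {
      i <- seq_len(n - k)
      ok <- keep[i] & keep[i + k]
      if (!any(ok)) next
      sums[k] <- sums[k] + sum(block$mat[cbind(i[ok], i[ok] + k)])
      cnts[k] <- cnts[k] + sum(ok)
    }
    if (n > 1) any_cis <- TRUE
  }
  if (!any_cis || all(cnts == 0))
    stop("matrix has no intra-chromosomal data")
  smin <- s_min_bins * bs
  smax <- (nmax - 1) * bs
  nb <- ceiling((log10(smax) - log10(smin)) * log_bins_per_decade)
  edges <- 10^(log10(smin) + (0:nb) / log_bins_per_decade)
  sep_bp <- seq_len(nmax - 1) * bs
  idx <- findInterval(sep_bp, edges, rightmost.closed = TRUE)
  use <- idx >= 1 & idx <= nb & sep_bp >= smin
  P <- Sn <- Cn <- numeric(nb)
  for (b in unique(idx[use])) {
    w <- use & idx == b
    Sn[b] <- sum(sums[w]); Cn[b] <- sum(cnts[w])
  }
  nonempty <- Cn > 0
  P[nonempty] <- Sn[nonempty] / Cn[nonempty]
  centers <- sqrt(edges[-1] * edges[-(nb + 1)])
  widths <- diff(edges)
  area <- sum(P[nonempty] * widths[nonempty])
  P <- P / area
  ps_curve(centers[nonempty], P[nonempty], npairs = Cn[nonempty],
           normalized = TRUE)
}

#' Loess smoothing of log10 P(s) against log10 s
#'
#' Local linear regression (tricube weights, degree 1) of log10 P on
#' log10 s at the stated span, evaluated on the input grid. A power law
#' (a line in log-log space) is reproduced exactly.
#'
#' @param ps a [ps_curve()].
#' @param span Loess span in (0, 1] (default 0.3).
#' @return object of class `derivative_curve` holding the smoothed values
#'   (derivatives are added by [ps_slope()] and [transition_point()]).
#' @export
loess_log_smooth <- function(ps, span = 0.3) {
  stopifnot(inherits(ps, "ps_curve"))
  if (span <= 0 || span > 1) stop("span must be in (0, 1]")
  tab <- ps$table[ps$table$P > 0 & ps$table$npairs > 0, ]
  if (nrow(tab) < 8) stop("need >= 8 distance bins with data")
  u <- log10(tab$s)
  y <- log10(tab$P)
  # span 1 with degree 1 is the global least-squares line
  fit <- stats::loess(y ~ u, span = span, degree = 1,
                      family = "gaussian", surface = "direct",
                      control = stats::loess.control(statistics = "none"))
  smooth <- stats::predict(fit, newdata = data.frame(u = u))
  structure(list(table = data.frame(log10_s = u, log10_P = y,
                                    log10_P_smooth = smooth),
                 span = span),
            class = "derivative_curve")
}

#' @export
print.derivative_curve <- function(x, ...) {
  cat("<derivative_curve> ", nrow(x$table), " grid points, span ",
      x$span, if ("slope" %in% names(x$table)) ", with derivatives" else "",
      "\n", sep = "")
  invisible(x)
}

# centered finite differences on a (possibly uneven) grid, one-sided at
# the boundaries
finite_diff <- function(x, y) {
  n <- length(x)
  d <- numeric(n)
  d[1] <- (y[2] - y[1]) / (x[2] - x[1])
  d[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    d[i] <- (y[i + 1] - y[i - 1]) / (x[i + 1] - x[i - 1])
  }
  d
}

#' First derivative (slope) of the smoothed log-log P(s) curve
#'
#' Centered finite differences of smoothed log10 P with respect to
#' log10 s; one-sided at the boundaries. The slope of a power law s^a is
#' the constant a.
#'
#' @param dc a `derivative_curve` from [loess_log_smooth()].
#' @return the curve with a `slope` column added.
#' @export
ps_slope <- function(dc) {
  stopifnot(inherits(dc, "derivative_curve"))
  if (nrow(dc$table) < 3) stop("need >= 3 points for derivatives")
  dc$table$slope <- finite_diff(dc$table$log10_s,
                                dc$table$log10_P_smooth)
  dc
}

#' Transition point ("shoulder") of P(s) from the second derivative
#'
#' Locates the minimum of the second derivative of smoothed log10 P(s) -
#' the point of maximal downward curvature, where the shoulder created by
#' contacts shorter than the chromatin loop length rolls over. Returns no
#' transition when the absolute curvature never reaches
#' `curvature_floor`, as on a pure power law.
#'
#' @param dc a `derivative_curve` (slope added automatically if absent).
#' @param window optional c(lo, hi) search window in bp.
#' @param curvature_floor minimal |second derivative| (per decade^2) to
#'   declare a transition (default 0.05).
#' @return object of class `transition_point`: `s_star` in bp (NA when
#'   none), `curvature`, `window`, and the curve with `curvature` column.
#' @export
transition_point <- function(dc, window = NULL, curvature_floor = 0.05) {
  stopifnot(inherits(dc, "derivative_curve"))
  if (!"slope" %in% names(dc$table)) dc <- ps_slope(dc)
  tab <- dc$table
  if (nrow(tab) < 5) stop("need >= 5 points for the second derivative")
  tab$curvature <- finite_diff(tab$log10_s, tab$slope)
  interior <- seq(2, nrow(tab) - 1)
  s_bp <- 10^tab$log10_s
  if (!is.null(window)) {
    if (window[1] >= max(s_bp) || window[2] <= min(s_bp))
      stop("window outside data range")
    interior <- interior[s_bp[interior] >= window[1] &
                           s_bp[interior] <= window[2]]
    if (!length(interior)) stop("window outside data range")
  }
  curv <- tab$curvature[interior]
  if (max(abs(curv)) < curvature_floor) {
    res <- list(s_star = NA_real_, curvature = NA_real_,
                window = window, rule = "second_derivative_minimum",
                table = tab)
  } else {
    k <- interior[which.min(curv)]
    res <- list(s_star = s_bp[k], curvature = tab$curvature[k],
                window = window, rule = "second_derivative_minimum",
                table = tab)
  }
  structure(res, class = "transition_point")
}

#' @export
print.transition_point <- function(x, ...) {
  if (is.na(x$s_star)) {
    cat("<transition_point> none (|curvature| below floor)\n")
  } else {
    cat("<transition_point> s* = ", format(round(x$s_star), big.mark = ","),
        " bp (curvature ", signif(x$curvature, 3), " per decade^2)\n",
        sep = "")
  }
  invisible(x)
}
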