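# Punctate loop (dot) calling: Poisson upper-tail test of raw counts
# against bias-rescaled local expecteds from four neighborhood models
# (donut, lower-left, horizontal, vertical), lambda-chunked FDR control,
# 8-connected clustering and centroid merging.

#' Loop caller configuration
#'
#' Defaults mirror the study's configuration (2 kb resolution, KR
#' normalization, FDR 0.01, peak half-width 3 bins, donut half-width 7
#' bins, merge distance 10 kb).
#'
#' @param resolution bin size in bp.
#' @param fdr false discovery rate within each lambda chunk.
#' @param peak_width peak-box half-width p, in bins.
#' @param donut_width donut half-width, in bins (must exceed
#'   `peak_width`).
#' @param merge_dist calls with centroids within this distance (bp,
#'   Euclidean) of a stronger call are absorbed.
#' @param min_dist_bins,max_dist_bp searched separation band.
#' @param fold_donut,fold_ll,fold_h,fold_v minimum observed/expected fold
#'   enrichment per model.
#' @return object of class `loop_caller_config`.
#' @export
loop_caller_config <- function(resolution = 2000, fdr = 0.01,
                               peak_width = 3, donut_width = 7,
                               merge_dist = 10000, min_dist_bins = 4,
                               max_dist_bp = 1e6, fold_donut = 1.75,
                               fold_ll = 1.75, fold_h = 1.5,
                               fold_v = 1.5) {
  if (!(donut_width > peak_width && peak_width > 0))
    stop("need donut_width > peak_width > 0")
  if (fdr <= 0 || fdr >= 1) stop("fdr must be in (0,1)")
  if (merge_dist < 0) stop("merge_dist must be >= 0")
  structure(list(resolution = resolution, fdr = fdr,
                 peak_width = peak_width, donut_width = donut_width,
                 merge_dist = merge_dist, min_dist_bins = min_dist_bins,
                 max_dist_bp = max_dist_bp, fold_donut = fold_donut,
                 fold_ll = fold_ll, fold_h = fold_h, fold_v = fold_v),
            class = "loop_caller_config")
}

# summed-area table: S[i+1, j+1] = sum(M[1:i, 1:j])
sat <- function(m) {
  s <- apply(m, 2, cumsum)
  s <- t(apply(s, 1, cumsum))
  rbind(0, cbind(0, s))
}

# vectorized clipped rectangle sum over a summed-area table
rsum <- function(S, r1, r2, c1, c2) {
  n <- nrow(S) - 1
  r1 <- pmax(r1, 1); c1 <- pmax(c1, 1)
  r2 <- pmin(r2, n); c2 <- pmin(c2, n)
  out <- numeric(length(r1))
  ok <- r2 >= r1 & c2 >= c1
  if (any(ok)) {
    i1 <- r1[ok]; i2 <- r2[ok]; j1 <- c1[ok]; j2 <- c2[ok]
    out[ok] <- S[cbind(i2 + 1, j2 + 1)] - S[cbind(i1, j2 + 1)] -
      S[cbind(i2 + 1, j1)] + S[cbind(i1, j1)]
  }
  out
}

# neighborhood sums for all four models at pixels (i, j); S is a
# summed-area table of an upper-triangle-only matrix, so cells at or
# below the diagonal contribute nothing (clipped at the diagonal).
model_sums <- function(S, i, j, p, w) {
  donut <- rsum(S, i - w, i + w, j - w, j + w) -
    rsum(S, i - p, i + p, j - p, j + p) -
    rsum(S, i, i, j - w, j + w) -
    rsum(S, i - w, i + w, j, j) +
    rsum(S, i, i, j - p, j + p) +
    rsum(S, i - p, i + p, j, j)
  ll <- rsum(S, i + 1, i + w, j - w, j - 1) -
    rsum(S, i + 1, i + p, j - p, j - 1)
  h <- rsum(S, i - 1, i + 1, j - w, j + w) -
    rsum(S, i - 1, i + 1, j - p, j + p)
  v <- rsum(S, i - w, i + w, j - 1, j + 1) -
    rsum(S, i - p, i + p, j - 1, j + 1)
  list(donut = donut, ll = ll, h = h, v = v)
}

# per-chromosome caller internals shared by call_loops and local_expected
chrom_loop_tables <- function(raw_block, bias, config) {
  C <- raw_block$mat
  n <- nrow(C)
  keep <- !raw_block$mask & !is.na(bias)
  b <- ifelse(is.na(bias), Inf, bias)
  N <- C / outer(b, b)          # KR-normalized values; masked rows -> 0
  V <- outer(keep, keep) * 1
  # distance expected on the normalized matrix, lowess-smoothed
  e <- distance_expected(list(mat = N, mask = !keep), exclude = 0)
  e[is.na(e)] <- 0
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  E <- matrix(0, n, n)
  E[sep > 0] <- e[sep[sep > 0]]
  E <- E * V
  ut <- upper.tri(matrix(0, n, n), diag = FALSE)
  Nu <- N * V; Nu[!ut] <- 0
  Eu <- E; Eu[!ut] <- 0
  Vu <- V; Vu[!ut] <- 0
  list(C = C, n = n, keep = keep, b = b, evec = e,
       SN = sat(Nu), SE = sat(Eu), SV = sat(Vu))
}

# lambda chunk index: powers of 2^(1/3)
lambda_chunk <- function(lambda) {
  k <- ceiling(3 * log2(pmax(lambda, 1e-12)))
  pmax(k, 0L)
}

#' Local expected values for one pixel under the four neighborhood models
#'
#' The expected is the neighborhood mean of KR-normalized counts rescaled
#' by the distance-decay expected at the pixel's separation, reported both
#' on the normalized scale and as a raw-count Poisson rate (rescaled by
#' the pixel's bias product).
#'
#' @param cm_raw a raw [contact_matrix()].
#' @param bias divisive KR bias vector (e.g. from [kr_balance()]).
#' @param chrom chromosome name.
#' @param i,j bin indices within the chromosome (j > i).
#' @param config a [loop_caller_config()].
#' @return list with `expected` and `lambda` (length-4 named vectors) and
#'   `observed`; NULL components where a neighborhood is entirely masked.
#' @export
local_expected <- function(cm_raw, bias, chrom, i, j, config) {
  rg <- chrom_bin_range(cm_raw$bins, chrom)
  idx <- rg[1]:rg[2]
  block <- cis_block(cm_raw, chrom)
  tabs <- chrom_loop_tables(block, bias[idx], config)
  p <- config$peak_width; w <- config$donut_width
  SN <- model_sums(tabs$SN, i, j, p, w)
  SE <- model_sums(tabs$SE, i, j, p, w)
  SV <- model_sums(tabs$SV, i, j, p, w)
  eij <- if (j - i >= 1 && j - i <= length(tabs$evec))
    tabs$evec[j - i] else 0
  expected <- lambda <- stats::setNames(rep(NA_real_, 4),
                                        c("donut", "ll", "h", "v"))
  for (mdl in names(expected)) {
    if (SV[[mdl]] > 0 && SE[[mdl]] > 0) {
      expected[mdl] <- SN[[mdl]] / SE[[mdl]] * eij
      lambda[mdl] <- expected[mdl] * tabs$b[i] * tabs$b[j]
    }
  }
  list(observed = tabs$C[i, j], expected = expected, lambda = lambda)
}

#' Call punctate chromatin loops (dots)
#'
#' For every candidate pixel in the searched separation band, tests the
#' observed raw count against a bias-rescaled Poisson expected under each
#' of the four local models; p-values are BH-corrected within lambda
#' chunks (powers of 2^(1/3)) at FDR `config$fdr`. A call requires
#' significance under all four models plus the per-model fold floors.
#' Significant pixels are clustered by 8-connectivity; each cluster is
#' summarized by its strongest pixel, and calls whose centroids lie
#' within `merge_dist` of a stronger call are absorbed. Output is
#' deterministic for identical input.
#'
#' @param cm_raw a raw [contact_matrix()] at the configured resolution.
#' @param bias divisive KR bias vector; computed by [kr_balance()] when
#'   omitted (set `bias = NULL` explicitly to allow this).
#' @param config a [loop_caller_config()].
#' @return data.frame of class `loop_calls` in BEDPE-like layout: chrom,
#'   anchor intervals, observed, per-model expecteds and q-values, and
#'   `loop_length` (bp separation of the anchors).
#' @export
call_loops <- function(cm_raw, bias, config = loop_caller_config()) {
  stopifnot(inherits(cm_raw, "contact_matrix"),
            inherits(config, "loop_caller_config"))
  if (cm_raw$norm != "raw") stop("call_loops expects raw counts")
  bs <- binsize_of(cm_raw$bins)
  if (bs != config$resolution)
    stop("matrix resolution does not match config")
  if (missing(bias)) stop("bias vector required (pass NULL to compute)")
  if (is.null(bias)) bias <- kr_balance(cm_raw)$bias
  layout <- attr(cm_raw$bins, "layout")
  p <- config$peak_width; w <- config$donut_width
  max_sep <- floor(config$max_dist_bp / bs)
  per_chrom <- list()
  for (ch in layout$chromosomes$name) {
    rg <- chrom_bin_range(cm_raw$bins, ch)
    idx <- rg[1]:rg[2]
    block <- cis_block(cm_raw, ch)
    tabs <- chrom_loop_tables(block, bias[idx], config)
    n <- tabs$n
    cand <- which(tabs$C > 0 & upper.tri(tabs$C), arr.ind = TRUE)
    sepc <- cand[, 2] - cand[, 1]
    ok <- sepc >= config$min_dist_bins & sepc <= max_sep &
      tabs$keep[cand[, 1]] & tabs$keep[cand[, 2]]
    cand <- cand[ok, , drop = FALSE]
    if (!nrow(cand)) next
    i <- cand[, 1]; j <- cand[, 2]
    SN <- model_sums(tabs$SN, i, j, p, w)
    SE <- model_sums(tabs$SE, i, j, p, w)
    SV <- model_sums(tabs$SV, i, j, p, w)
    eij <- tabs$evec[j - i]
    obs <- tabs$C[cbind(i, j)]
    lam <- list()
    valid <- rep(TRUE, length(i))
    for (mdl in c("donut", "ll", "h", "v")) {
      good <- SV[[mdl]] > 0 & SE[[mdl]] > 0
      lmb <- rep(NA_real_, length(i))
      lmb[good] <- SN[[mdl]][good] / SE[[mdl]][good] * eij[good] *
        tabs$b[i][good] * tabs$b[j][good]
      lam[[mdl]] <- lmb
      valid <- valid & good & lmb > 0
    }
    per_chrom[[ch]] <- data.frame(
      chrom = ch, i = i, j = j, obs = obs,
      l_donut = lam$donut, l_ll = lam$ll, l_h = lam$h, l_v = lam$v,
      valid = valid, stringsAsFactors = FALSE)
  }
  if (!length(per_chrom)) return(empty_loop_calls(config, bs))
  px <- do.call(rbind, per_chrom)
  px <- px[px$valid, , drop = FALSE]
  if (!nrow(px)) return(empty_loop_calls(config, bs))
  # Poisson upper tail, BH within lambda chunks, per model
  for (mdl in c("donut", "ll", "h", "v")) {
    lmb <- px[[paste0("l_", mdl)]]
    pval <- stats::ppois(px$obs - 1, lmb, lower.tail = FALSE)
    qv <- rep(NA_real_, length(pval))
    for (ck in unique(lambda_chunk(lmb))) {
      wck <- lambda_chunk(lmb) == ck
      qv[wck] <- stats::p.adjust(pval[wck], method = "BH")
    }
    px[[paste0("q_", mdl)]] <- qv
  }
  sig <- px$q_donut <= config$fdr & px$q_ll <= config$fdr &
    px$q_h <= config$fdr & px$q_v <= config$fdr &
    px$obs >= config$fold_donut * px$l_donut &
    px$obs >= config$fold_ll * px$l_ll &
    px$obs >= config$fold_h * px$l_h &
    px$obs >= config$fold_v * px$l_v
  px <- px[sig, , drop = FALSE]
  if (!nrow(px)) return(empty_loop_calls(config, bs))
  calls <- do.call(rbind, lapply(split(px, px$chrom), function(d) {
    cl <- cluster_pixels(d$i, d$j)
    do.call(rbind, lapply(split(d, cl), function(g) {
      strength <- g$obs / g$l_donut
      best <- order(-strength, g$i, g$j)[1]
      g$n_pixels <- nrow(g)
      g[best, , drop = FALSE]
    }))
  }))
  calls <- merge_calls(calls, config$merge_dist / bs)
  loop_calls_frame(calls, cm_raw$bins, config)
}

# 8-connected components of a pixel set
cluster_pixels <- function(i, j) {
  n <- length(i)
  key <- paste(i, j)
  lookup <- stats::setNames(seq_len(n), key)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in order(i, j)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s; comp[s] <- cur
    off <- expand.grid(di = -1:1, dj = -1:1)
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nbk <- paste(i[v] + off$di, j[v] + off$dj)
      hit <- lookup[nbk]
      hit <- hit[!is.na(hit)]
      hit <- hit[is.na(comp[hit])]
      comp[hit] <- cur
      queue <- c(queue, hit)
    }
  }
  comp
}

# absorb calls whose centroid lies within `radius` bins (Euclidean) of a
# stronger kept call; running this twice changes nothing
merge_calls <- function(calls, radius) {
  strength <- calls$obs / calls$l_donut
  ord <- order(-strength, calls$chrom, calls$i, calls$j)
  calls <- calls[ord, , drop = FALSE]
  keep <- logical(nrow(calls))
  for (k in seq_len(nrow(calls))) {
    kept <- which(keep & calls$chrom == calls$chrom[k])
    if (!length(kept)) { keep[k] <- TRUE; next }
    dd <- sqrt((calls$i[kept] - calls$i[k])^2 +
                 (calls$j[kept] - calls$j[k])^2)
    keep[k] <- all(dd > radius)
  }
  out <- calls[keep, , drop = FALSE]
  out[order(out$chrom, out$i, out$j), , drop = FALSE]
}

empty_loop_calls <- function(config, bs) {
  loop_calls_frame(NULL, NULL, config)
}

loop_calls_frame <- function(calls, bins, config) {
  cols <- c("chrom", "start1", "end1", "start2", "end2", "observed",
            "e_donut", "e_ll", "e_h", "e_v",
            "q_donut", "q_ll", "q_h", "q_v", "loop_length", "n_pixels")
  if (is.null(calls) || !nrow(calls)) {
    out <- as.data.frame(stats::setNames(
      replicate(length(cols), numeric(0), simplify = FALSE), cols))
    out$chrom <- character(0)
  } else {
    bs <- binsize_of(bins)
    off <- chrom_offsets(bins)[calls$chrom]
    li <- calls$i; lj <- calls$j
    gi <- off + li; gj <- off + lj
    out <- data.frame(
      chrom = calls$chrom,
      start1 = bins$start[gi], end1 = bins$end[gi],
      start2 = bins$start[gj], end2 = bins$end[gj],
      observed = calls$obs,
      e_donut = calls$l_donut, e_ll = calls$l_ll,
      e_h = calls$l_h, e_v = calls$l_v,
      q_donut = calls$q_donut, q_ll = calls$q_ll,
      q_h = calls$q_h, q_v = calls$q_v,
      loop_length = (lj - li) * bs,
      n_pixels = calls$n_pixels,
      stringsAsFactors = FALSE)
    rownames(out) <- NULL
  }
  attr(out, "config") <- config
  class(out) <- c("loop_calls", "data.frame")
  out
}

#' Write loop calls as BEDPE
#' @param calls a `loop_calls` data.frame from [call_loops()].
#' @param path output path.
#' @export
write_bedpe <- function(calls, path) {
  df <- data.frame(calls$chrom, calls$start1, calls$end1,
                   calls$chrom, calls$start2, calls$end2,
                   calls$observed,
                   format(calls$e_donut, digits = 10),
                   format(calls$e_ll, digits = 10),
                   format(calls$e_h, digits = 10),
                   format(calls$e_v, digits = 10),
                   format(calls$q_donut, digits = 10),
                   format(calls$q_ll, digits = 10),
                   format(calls$q_h, digits = 10),
                   format(calls$q_v, digits = 10))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Loops-per-length histogram
#'
#' Histogram of loop lengths normalized per Mb of genome assayed, as used
#' to compare loop-size distributions between strains.
#'
#' @param calls a `loop_calls` data.frame.
#' @param layout a [genome_layout()] (provides the genome length).
#' @param breaks loop-length bin edges in bp.
#' @return data.frame of class `loops_per_length` with `length_lo`,
#'   `length_hi`, `count`, `per_mb`.
#' @export
loops_per_length <- function(calls, layout,
                             breaks = seq(0, 1e5, by = 1e4)) {
  genome_mb <- sum(layout$chromosomes$length) / 1e6
  counts <- if (nrow(calls)) {
    ll <- calls$loop_length[calls$loop_length > min(breaks) &
                              calls$loop_length <= max(breaks)]
    tabulate(findInterval(ll, breaks, left.open = TRUE),
             nbins = length(breaks) - 1)
  } else rep(0, length(breaks) - 1)
  out <- data.frame(length_lo = breaks[-length(breaks)],
                    length_hi = breaks[-1],
                    count = counts, per_mb = counts / genome_mb)
  class(out) <- c("loops_per_length", "data.frame")
  out
}
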