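# Synthetic Hi-C generator: power-law distance decay with planted bouquet
# arm alignment (anti-diagonal band), Rabl centromere / telomere
# clustering on trans contacts, grid-like cohesin loop dots between
# nearby anchors, and Poisson sequencing-depth sampling - with a full
# ground-truth record for recovery tests.

#' Default toy genome for simulations
#'
#' Three chromosomes of 4, 3 and 2 Mb (about a quarter of the fission
#' yeast genome, so the whole pipeline runs in seconds) with central
#' 40 kb centromeres and 60 kb telomere margins. `scale = 4` gives a
#' genome of real fission-yeast dimensions for performance tests.
#'
#' @param scale multiplier on chromosome lengths.
#' @return a [genome_layout()].
#' @export
toy_genome <- function(scale = 1) {
  len <- c(chrI = 4e6, chrII = 3e6, chrIII = 2e6) * scale
  cen <- data.frame(chrom = names(len),
                    start = len / 2 - 2e4, end = len / 2 + 2e4)
  genome_layout(len, centromeres = cen, telomere_margin = 6e4)
}

#' Simulation configuration
#'
#' All planted-signal parameters of the generator. Enrichments are
#' multiplicative: a planted feature with enrichment `beta` multiplies
#' the background intensity by `1 + beta` at its center (so the default
#' `loop_enrich = 4` plants 5x dots).
#'
#' @param layout a [genome_layout()]; default [toy_genome()].
#' @param binsize simulation resolution in bp.
#' @param alpha distance-decay exponent of the cis background
#'   (intensity ~ s^-alpha, default 1).
#' @param align_extent bouquet arm-alignment extent in bp, scalar or one
#'   value per chromosome; each must not exceed the chromosome's shorter
#'   arm. 0 disables.
#' @param align_enrich anti-diagonal band enrichment beta.
#' @param align_band band half-width of the planted anti-diagonal signal,
#'   in bins.
#' @param rabl_enrich centromere-centromere trans enrichment beta.
#' @param telo_enrich telomere-telomere trans enrichment beta.
#' @param anchors named list of per-chromosome anchor positions (bp), or
#'   NULL to place anchors every `anchor_spacing` bp along both arms.
#' @param anchor_spacing spacing of the default anchor grid (bp; the
#'   wild-type loop scale is about 20 kb).
#' @param loop_enrich dot enrichment beta at anchor-pair grid points.
#' @param dot_halfwidth half-width of each planted dot in bins.
#' @param loop_reach anchors up to `loop_reach` neighbors apart interact:
#'   1 for wild-type-like short loops, 2 for wpl1-delta-like fused loops,
#'   0 for rec8-delta-like loss of loops.
#' @param depth expected total pair count N.
#' @param trans_fraction fraction of total intensity mass placed on
#'   inter-chromosomal (trans) pixels.
#' @param seed random seed recorded in the ground truth.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(layout = toy_genome(), binsize = 20000, alpha = 1,
                       align_extent = 9e5, align_enrich = 3,
                       align_band = 1, rabl_enrich = 3, telo_enrich = 3,
                       anchors = NULL, anchor_spacing = 2e4,
                       loop_enrich = 4, dot_halfwidth = 1,
                       loop_reach = 1, depth = 1e6,
                       trans_fraction = 0.15, seed = 1) {
  stopifnot(inherits(layout, "genome_layout"))
  nchrom <- nrow(layout$chromosomes)
  align_extent <- rep_len(align_extent, nchrom)
  arms <- vapply(seq_len(nchrom), function(i) {
    L <- layout$chromosomes$length[i]
    if (is.null(layout$centromeres)) return(L / 2)
    cen <- layout$centromeres[
      layout$centromeres$chrom == layout$chromosomes$name[i], ]
    if (nrow(cen) != 1) return(L / 2)
    min(cen$start, L - cen$end)
  }, numeric(1))
  if (any(align_extent > arms))
    stop("align_extent exceeds an arm length")
  if (any(c(align_enrich, rabl_enrich, telo_enrich, loop_enrich) < 0))
    stop("enrichments must be >= 0")
  if (depth < 0) stop("depth must be >= 0")
  if (trans_fraction < 0 || trans_fraction >= 1)
    stop("trans_fraction must be in [0, 1)")
  structure(list(layout = layout, binsize = binsize, alpha = alpha,
                 align_extent = align_extent,
                 align_enrich = align_enrich, align_band = align_band,
                 rabl_enrich = rabl_enrich, telo_enrich = telo_enrich,
                 anchors = anchors, anchor_spacing = anchor_spacing,
                 loop_enrich = loop_enrich,
                 dot_halfwidth = dot_halfwidth, loop_reach = loop_reach,
                 depth = depth, trans_fraction = trans_fraction,
                 seed = seed),
            class = "sim_config")
}

#' Simulator presets named after the study conditions they emulate
#'
#' `wt` (and `rec10d`, whose maps look wild-type-like): short loops
#' between adjacent anchors and full bouquet alignment. `wpl1d`: loop
#' reach 2 (fused, longer loops) with weakened arm alignment. `rec8d`:
#' no loops and near-zero alignment. `vg`: vegetative growth - Rabl
#' centromere clustering, no bouquet, no meiotic loops.
#'
#' @param preset one of `"wt"`, `"wpl1d"`, `"rec8d"`, `"rec10d"`, `"vg"`.
#' @param ... overrides passed to [sim_config()].
#' @return a [sim_config()].
#' @export
sim_preset <- function(preset = c("wt", "wpl1d", "rec8d", "rec10d", "vg"),
                       ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    wt = list(),
    rec10d = list(),
    wpl1d = list(loop_reach = 2, align_enrich = 1.5),
    rec8d = list(loop_enrich = 0, align_enrich = 0.2, telo_enrich = 3),
    vg = list(loop_enrich = 0, align_enrich = 0, align_extent = 0,
              rabl_enrich = 5, telo_enrich = 0))
  over <- list(...)
  args[names(over)] <- over
  cfg <- do.call(sim_config, args)
  cfg$preset <- preset
  cfg
}

# anchor bin indices (within chromosome) for one chromosome
anchor_bins <- function(cfg, ch) {
  L <- chrom_length(cfg$layout, ch)
  pos <- if (!is.null(cfg$anchors)) {
    cfg$anchors[[ch]]
  } else {
    seq(cfg$anchor_spacing, L - cfg$anchor_spacing,
        by = cfg$anchor_spacing)
  }
  if (is.null(pos) || !length(pos)) return(integer(0))
  sort(unique(pmin(floor(pos / cfg$binsize) + 1L,
                   ceiling(L / cfg$binsize))))
}

#' Expected-intensity surface and ground truth of a simulation
#'
#' Composes the rate model: cis intensity
#' `s^-alpha * (1 + align_enrich * anti-diagonal band) *
#' (1 + loop_enrich * dot kernel)`; trans intensity is flat with additive
#' centromere-centromere and telomere-telomere enrichment blocks, scaled
#' so the trans mass fraction matches the configuration. Strictly
#' positive and symmetric.
#'
#' @param cfg a [sim_config()].
#' @return list with `intensity` (dense genome-wide matrix), `bins` (a
#'   [bin_table()]) and `truth` (class `sim_truth`: planted anchor bin
#'   pairs, per-chromosome alignment extent, exponent, seed).
#' @export
expected_intensity <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  bins <- bin_table(cfg$layout, cfg$binsize)
  nb <- nrow(bins)
  M <- matrix(0, nb, nb)
  chroms <- cfg$layout$chromosomes$name
  truth_anchors <- list()
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    rg <- chrom_bin_range(bins, ch)
    n <- rg[2] - rg[1] + 1
    ii <- matrix(seq_len(n), n, n)
    jj <- t(ii)
    s <- pmax(abs(ii - jj), 0.5)
    block <- s^(-cfg$alpha)
    if (cfg$align_enrich > 0 && cfg$align_extent[ci] > 0) {
      a_bins <- cfg$align_extent[ci] / cfg$binsize
      d <- (pmin(ii, jj) + (n + 1 - pmax(ii, jj))) / 2
      band <- abs(ii + jj - (n + 1)) <= cfg$align_band & d <= a_bins
      block <- block * (1 + cfg$align_enrich * band)
    }
    anch <- anchor_bins(cfg, ch)
    planted <- NULL
    if (cfg$loop_enrich > 0 && cfg$loop_reach >= 1 && length(anch) > 1) {
      K <- matrix(0, n, n)
      hw <- cfg$dot_halfwidth
      sigma <- max(hw / 1.2, 0.5)
      kern <- outer((-hw):hw, (-hw):hw, function(a, b)
        exp(-(a^2 + b^2) / (2 * sigma^2)))
      nr <- length(anch)
      pr <- list()
      for (r in seq_len(nr - 1)) {
        for (q in (r + 1):min(r + cfg$loop_reach, nr)) {
          ai <- anch[r]; aj <- anch[q]
          rr <- (ai - hw):(ai + hw); cc <- (aj - hw):(aj + hw)
          okr <- rr >= 1 & rr <= n; okc <- cc >= 1 & cc <= n
          K[rr[okr], cc[okc]] <- pmax(K[rr[okr], cc[okc], drop = FALSE],
                                      kern[okr, okc, drop = FALSE])
          pr[[length(pr) + 1]] <- c(ai, aj)
        }
      }
      K[lower.tri(K)] <- t(K)[lower.tri(K)]
      block <- block * (1 + cfg$loop_enrich * K)
      planted <- do.call(rbind, pr)
    }
    M[rg[1]:rg[2], rg[1]:rg[2]] <- block
    truth_anchors[[ch]] <- planted
  }
  # trans: flat base with additive centromere/telomere clustering blocks
  if (cfg$trans_fraction > 0 && length(chroms) > 1) {
    trans_unit <- matrix(0, nb, nb)
    chrom_of <- bins$chrom
    cis_same <- outer(chrom_of, chrom_of, "==")
    trans_unit[!cis_same] <- 1
    if (cfg$rabl_enrich > 0 && !is.null(cfg$layout$centromeres)) {
      cb <- region_bins(bins, centromere_regions(cfg$layout))
      trans_unit[cb, cb] <- trans_unit[cb, cb] * (1 + cfg$rabl_enrich)
    }
    if (cfg$telo_enrich > 0) {
      tb <- region_bins(bins, telomere_regions(cfg$layout))
      trans_unit[tb, tb] <- trans_unit[tb, tb] * (1 + cfg$telo_enrich)
    }
    trans_unit[cis_same] <- 0
    cis_mass <- sum(M)
    scale <- cfg$trans_fraction / (1 - cfg$trans_fraction) *
      cis_mass / sum(trans_unit)
    M <- M + trans_unit * scale
  }
  truth <- structure(list(anchors = truth_anchors,
                          align_extent = stats::setNames(
                            cfg$align_extent, chroms),
                          alpha = cfg$alpha, seed = cfg$seed,
                          config = cfg),
                     class = "sim_truth")
  list(intensity = M, bins = bins, truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  na <- sum(vapply(x$anchors,
                   function(a) if (is.null(a)) 0L else nrow(a),
                   integer(1)))
  cat("<sim_truth> ", na, " planted anchor pairs; extents ",
      paste(signif(x$align_extent / 1e6, 3), collapse = "/"),
      " Mb; alpha ", x$alpha, "; seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Poisson-sample a raw contact matrix from an intensity surface
#'
#' Independent Poisson draws on the upper triangle with means
#' proportional to the intensity, scaled so the total expected count is
#' `depth`. Identical seeds give identical matrices.
#'
#' @param intensity output of [expected_intensity()] (or a compatible
#'   list with `intensity` and `bins`).
#' @param depth expected total pair count.
#' @param seed random seed.
#' @return a raw [contact_matrix()].
#' @export
sample_matrix <- function(intensity, depth, seed) {
  M <- intensity$intensity
  if (any(!is.finite(M)) || any(M < 0))
    stop("intensities must be positive and finite")
  if (depth < 0) stop("depth must be >= 0")
  nb <- nrow(M)
  up <- which(upper.tri(M, diag = TRUE))
  mu <- M[up] / sum(M[up]) * depth
  counts <- withr_seed(seed, stats::rpois(length(up), mu))
  nz <- counts > 0
  ij <- arrayInd(up[nz], dim(M))
  m <- Matrix::sparseMatrix(i = ij[, 1], j = ij[, 2], x = counts[nz],
                            dims = c(nb, nb), symmetric = TRUE)
  contact_matrix(m, intensity$bins, norm = "raw")
}

# run expr under a local RNG seed without disturbing the caller's RNG
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a raw contact matrix in one step
#'
#' @param cfg a [sim_config()].
#' @param keep_intensity keep the dense intensity surface in the result.
#' @return list with `matrix` (raw [contact_matrix()]), `truth`, and
#'   optionally `intensity`.
#' @export
simulate_hic <- function(cfg, keep_intensity = FALSE) {
  ei <- expected_intensity(cfg)
  cm <- sample_matrix(ei, cfg$depth, cfg$seed)
  out <- list(matrix = cm, truth = ei$truth)
  if (keep_intensity) out$intensity <- ei$intensity
  out
}

#' Sample a read-pair table with planted contaminants
#'
#' Samples bin pairs from the intensity surface, places mates uniformly
#' within their bins with random strands and high MapQ, then adds the
#' configured fractions of PCR duplicates, low-MapQ pairs, same-fragment
#' (self-ligation) pairs and adjacent-fragment inward (undigested) pairs.
#' The truth record counts every planted category so the filter stage can
#' be audited end-to-end.
#'
#' @param cfg a [sim_config()].
#' @param fragmap a [fragment_map()] on the same layout.
#' @param rates named list with elements `duplicate`, `low_mapq`,
#'   `self_ligation`, `undigested`, each the fraction of the total output
#'   planted as that contaminant (all in \[0, 1\], summing below 1).
#' @return list with `pairs` (data.frame in [read_pairs()] layout) and
#'   `truth` (planted counts).
#' @export
sample_pairs <- function(cfg, fragmap,
                         rates = list(duplicate = 0, low_mapq = 0,
                                      self_ligation = 0,
                                      undigested = 0)) {
  stopifnot(inherits(cfg, "sim_config"), inherits(fragmap, "fragment_map"))
  r <- rates
  for (k in c("duplicate", "low_mapq", "self_ligation", "undigested"))
    if (is.null(r[[k]])) r[[k]] <- 0
  rv <- unlist(r[c("duplicate", "low_mapq", "self_ligation",
                   "undigested")])
  if (any(rv < 0) || any(rv > 1) || sum(rv) >= 1)
    stop("contaminant rates must lie in [0,1] and sum below 1")
  ei <- expected_intensity(cfg)
  bins <- ei$bins
  withr_seed(cfg$seed + 104729L, {
    N <- cfg$depth
    n_clean <- round(N * (1 - sum(rv)))
    n_cat <- round(N * rv)
    up <- which(upper.tri(ei$intensity, diag = TRUE))
    prob <- ei$intensity[up] / sum(ei$intensity[up])
    draw <- sample.int(length(up), n_clean, replace = TRUE, prob = prob)
    ij <- arrayInd(up[draw], dim(ei$intensity))
    mk_pos <- function(b) {
      floor(bins$start[b] + stats::runif(length(b)) *
              (bins$end[b] - bins$start[b]))
    }
    clean <- data.frame(
      chrom1 = bins$chrom[ij[, 1]], pos1 = mk_pos(ij[, 1]),
      strand1 = sample(c("+", "-"), n_clean, replace = TRUE),
      mapq1 = sample(30:60, n_clean, replace = TRUE),
      chrom2 = bins$chrom[ij[, 2]], pos2 = mk_pos(ij[, 2]),
      strand2 = sample(c("+", "-"), n_clean, replace = TRUE),
      mapq2 = sample(30:60, n_clean, replace = TRUE),
      stringsAsFactors = FALSE)
    parts <- list(clean)
    # PCR duplicates: copies of existing records
    if (n_cat[["duplicate"]] > 0) {
      src <- clean[sample.int(n_clean, n_cat[["duplicate"]],
                              replace = TRUE), ]
      parts <- c(parts, list(src))
    }
    # low-MapQ: like clean pairs but one mate below the threshold
    if (n_cat[["low_mapq"]] > 0) {
      k <- n_cat[["low_mapq"]]
      src <- clean[sample.int(n_clean, k, replace = TRUE), ]
      # random shift decollides from the source and from sibling copies
      src$pos1 <- pmax(src$pos1 - sample.int(199, k, replace = TRUE), 0)
      src$mapq1 <- sample(0:29, k, replace = TRUE)
      parts <- c(parts, list(src))
    }
    frag_pair <- function(k, adjacent) {
      ch <- sample(names(fragmap$fragments), k, replace = TRUE)
      out <- data.frame(chrom1 = ch, pos1 = 0, strand1 = "+",
                        mapq1 = sample(30:60, k, replace = TRUE),
                        chrom2 = ch, pos2 = 0, strand2 = "-",
                        mapq2 = sample(30:60, k, replace = TRUE),
                        stringsAsFactors = FALSE)
      for (w in seq_len(k)) {
        fr <- fragmap$fragments[[ch[w]]]
        len <- fr$end - fr$start
        cand <- if (adjacent) {
          which(len >= 1 & c(len[-1] >= 1, FALSE))  # f and f+1 non-empty
        } else {
          which(len >= 2)
        }
        f1 <- cand[sample.int(length(cand), 1)]
        f2 <- if (adjacent) f1 + 1L else f1
        p1 <- fr$start[f1] + sample.int(fr$end[f1] - fr$start[f1], 1) - 1
        p2 <- fr$start[f2] + sample.int(fr$end[f2] - fr$start[f2], 1) - 1
        if (!adjacent) { lo <- min(p1, p2); p2 <- max(p1, p2); p1 <- lo }
        out$pos1[w] <- p1; out$pos2[w] <- p2
      }
      out
    }
    # self-ligation: both mates on one fragment (inward after ordering)
    if (n_cat[["self_ligation"]] > 0)
      parts <- c(parts, list(frag_pair(n_cat[["self_ligation"]], FALSE)))
    # undigested: adjacent fragments, inward orientation
    if (n_cat[["undigested"]] > 0)
      parts <- c(parts, list(frag_pair(n_cat[["undigested"]], TRUE)))
    pairs <- do.call(rbind, parts)
    pairs <- pairs[sample.int(nrow(pairs)), ]
    pairs <- cbind(readID = sprintf("sim%08d", seq_len(nrow(pairs))),
                   pairs, stringsAsFactors = FALSE)
    rownames(pairs) <- NULL
    list(pairs = pairs[, c("readID", "chrom1", "pos1", "strand1",
                           "mapq1", "chrom2", "pos2", "strand2",
                           "mapq2")],
         truth = list(n_total = nrow(pairs), n_clean = n_clean,
                      planted = as.list(n_cat), rates = r,
                      seed = cfg$seed))
  })
}
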