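#' Restriction fragment map
#'
#' Per-chromosome sorted cut sites of a restriction enzyme and the derived
#' fragment tiling. The cut coordinate convention is the 0-based position
#' of the first base of the recognition site (MboI, GATC, cuts 5' of the
#' site), so a site starting at position 0 yields a zero-length leading
#' fragment; fragment count is always number of cuts + 1.
#'
#' @param cut_sites named list, one sorted numeric vector of 0-based cut
#'   positions per chromosome.
#' @param layout a [genome_layout()] providing chromosome lengths.
#' @return object of class `fragment_map`: per chromosome a data.frame of
#'   fragment `start`/`end` intervals.
#' @export
fragment_map <- function(cut_sites, layout) {
  stopifnot(inherits(layout, "genome_layout"), is.list(cut_sites))
  if (is.null(names(cut_sites)) ||
      !all(names(cut_sites) %in% layout$chromosomes$name))
    stop("cut_sites must be named by chromosomes present in the layout")
  frags <- lapply(names(cut_sites), function(ch) {
    cuts <- as.numeric(cut_sites[[ch]])
    L <- chrom_length(layout, ch)
    if (length(cuts)) {
      if (is.unsorted(cuts, strictly = TRUE))
        stop("cut sites must be strictly increasing on ", ch)
      if (any(cuts < 0) || any(cuts >= L))
        stop("cut site outside chromosome ", ch)
    }
    data.frame(start = c(0, cuts), end = c(cuts, L))
  })
  names(frags) <- names(cut_sites)
  structure(list(fragments = frags, cut_sites = cut_sites, layout = layout),
            class = "fragment_map")
}

#' @export
print.fragment_map <- function(x, ...) {
  n <- vapply(x$fragments, nrow, integer(1))
  cat("<fragment_map> ", length(n), " chromosomes, ",
      format(sum(n), big.mark = ","), " fragments\n", sep = "")
  invisible(x)
}

#' Build a fragment map from genome sequence
#'
#' Scans each chromosome for the restriction site (every occurrence yields
#' one cut at the match start) and derives the fragment tiling.
#'
#' @param sequences named character vector of chromosome sequences over
#'   A/C/G/T/N, a `Biostrings::DNAStringSet`, or a path to a FASTA file.
#' @param site recognition sequence; MboI's GATC by default.
#' @param telomere_margin passed to the derived [genome_layout()].
#' @return a [fragment_map()].
#' @examples
#' fm <- build_fragment_map(c(chrT = "AAGATCAA"), telomere_margin = 1)
#' fm$fragments$chrT  # two fragments, cut before the G of GATC
#' @export
build_fragment_map <- function(sequences, site = "GATC",
                               telomere_margin = 6e4) {
  if (is.character(sequences) && length(sequences) == 1 &&
      is.null(names(sequences)) && file.exists(sequences))
    sequences <- Biostrings::readDNAStringSet(sequences)
  if (is.character(sequences)) {
    if (is.null(names(sequences))) stop("sequences must be named")
    sequences <- Biostrings::DNAStringSet(toupper(sequences))
  }
  if (!methods::is(sequences, "DNAStringSet"))
    stop("sequences must be a named character vector, DNAStringSet or FASTA path")
  if (any(Biostrings::width(sequences) == 0)) stop("empty sequence")
  # fixed=TRUE: N never matches, as in fragment maps built from assemblies
  hits <- lapply(seq_along(sequences), function(i)
    Biostrings::start(Biostrings::matchPattern(
      site, sequences[[i]], fixed = TRUE)) - 1)
  names(hits) <- names(sequences)
  layout <- genome_layout(
    stats::setNames(Biostrings::width(sequences), names(sequences)),
    telomere_margin = min(telomere_margin,
                          floor(min(Biostrings::width(sequences)) / 2) - 1))
  fragment_map(hits, layout)
}

#' Assign read-pair mates to restriction fragments
#'
#' Each mate receives the 1-based index (within its chromosome) of the
#' fragment containing its 5' position; positions at a fragment start
#' belong to that fragment. Mates on chromosomes absent from the map or
#' outside the chromosome get NA and are later counted as
#' repetitive/unassigned by [filter_pairs()].
#'
#' @param pairs data.frame with columns `chrom1`, `pos1`, `chrom2`, `pos2`
#'   (0-based positions).
#' @param fragmap a [fragment_map()].
#' @return `pairs` with added integer columns `frag1`, `frag2`.
#' @export
assign_fragments <- function(pairs, fragmap) {
  stopifnot(inherits(fragmap, "fragment_map"))
  one <- function(chrom, pos) {
    out <- rep(NA_integer_, length(pos))
    for (ch in unique(chrom)) {
      if (!ch %in% names(fragmap$fragments)) next
      fr <- fragmap$fragments[[ch]]
      w <- which(chrom == ch & pos >= 0 & pos < fr$end[nrow(fr)])
      if (!length(w)) next
      # rightmost match handles zero-length leading fragments
      out[w] <- findInterval(pos[w], fr$start, rightmost.closed = FALSE)
    }
    out
  }
  pairs$frag1 <- one(pairs$chrom1, pairs$pos1)
  pairs$frag2 <- one(pairs$chrom2, pairs$pos2)
  pairs
}
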