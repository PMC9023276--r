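#' Genome layout: chromosomes, centromeres, telomere margins
#'
#' Defines the coordinate frame used by all downstream analyses. All
#' intervals are 0-based, half-open; 1-based coordinates appear only in
#' text formats that require them.
#'
#' @param chromosomes either a named numeric vector of chromosome lengths
#'   (bp) or a data.frame with columns `name` and `length`.
#' @param centromeres optional data.frame with columns `chrom`, `start`,
#'   `end` (0-based half-open) giving one centromere interval per
#'   chromosome.
#' @param telomere_margin width in bp of the region at each chromosome end
#'   treated as "telomere" for clustering statistics. Must be smaller than
#'   half of every chromosome.
#' @return an object of class `genome_layout`.
#' @examples
#' gl <- genome_layout(c(chrI = 4e6, chrII = 3e6))
#' @export
genome_layout <- function(chromosomes, centromeres = NULL,
                          telomere_margin = 6e4) {
  if (is.data.frame(chromosomes)) {
    stopifnot(all(c("name", "length") %in% names(chromosomes)))
    chroms <- data.frame(name = as.character(chromosomes$name),
                         length = as.numeric(chromosomes$length),
                         stringsAsFactors = FALSE)
  } else {
    if (is.null(names(chromosomes)) || any(names(chromosomes) == ""))
      stop("chromosome lengths must be named")
    chroms <- data.frame(name = names(chromosomes),
                         length = as.numeric(chromosomes),
                         stringsAsFactors = FALSE)
  }
  if (any(chroms$length <= 0)) stop("chromosome lengths must be > 0")
  if (anyDuplicated(chroms$name)) stop("duplicated chromosome names")
  if (!is.null(centromeres)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(centromeres)))
    centromeres <- centromeres[, c("chrom", "start", "end")]
    centromeres$chrom <- as.character(centromeres$chrom)
    m <- match(centromeres$chrom, chroms$name)
    if (anyNA(m)) stop("centromere on unknown chromosome")
    bad <- centromeres$start < 0 | centromeres$end > chroms$length[m] |
      centromeres$start >= centromeres$end
    if (any(bad)) stop("centromere interval outside chromosome")
  }
  if (any(telomere_margin >= chroms$length / 2))
    stop("telomere_margin must be < length/2 for every chromosome")
  structure(list(chromosomes = chroms, centromeres = centromeres,
                 telomere_margin = telomere_margin),
            class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("<genome_layout> ", nrow(x$chromosomes), " chromosomes, ",
      format(sum(x$chromosomes$length), big.mark = ","), " bp total\n",
      sep = "")
  for (i in seq_len(nrow(x$chromosomes)))
    cat("  ", x$chromosomes$name[i], ": ",
        format(x$chromosomes$length[i], big.mark = ","), " bp\n", sep = "")
  cat("  telomere margin: ", x$telomere_margin, " bp; centromeres: ",
      if (is.null(x$centromeres)) "none" else "annotated", "\n", sep = "")
  invisible(x)
}

chrom_length <- function(layout, chrom) {
  i <- match(chrom, layout$chromosomes$name)
  if (anyNA(i)) stop("unknown chromosome: ", paste(chrom[is.na(i)],
                                                   collapse = ", "))
  layout$chromosomes$length[i]
}

#' Telomere margin regions of a genome layout
#'
#' Two intervals per chromosome (one at each end) of width
#' `telomere_margin`.
#'
#' @param layout a [genome_layout()].
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @export
telomere_regions <- function(layout) {
  ch <- layout$chromosomes
  m <- layout$telomere_margin
  data.frame(chrom = rep(ch$name, each = 2),
             start = as.vector(rbind(0, ch$length - m)),
             end = as.vector(rbind(m, ch$length)),
             stringsAsFactors = FALSE)
}

#' Centromere regions of a genome layout
#' @param layout a [genome_layout()] with centromere annotations.
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @export
centromere_regions <- function(layout) {
  if (is.null(layout$centromeres)) stop("layout has no centromere annotation")
  layout$centromeres
}

#' Non-overlapping genomic bin table at a fixed resolution
#'
#' Tiles every chromosome with half-open bins of width `binsize`; the last
#' bin of each chromosome may be short. Bins carry a global 1-based index
#' used by all contact matrices.
#'
#' @param layout a [genome_layout()].
#' @param binsize bin width in bp (the study's resolutions are 20000, 5000
#'   and 2000).
#' @return data.frame of class `bin_table` with columns `chrom`, `start`,
#'   `end`, `bin`, and attributes `binsize` and `layout`.
#' @export
bin_table <- function(layout, binsize) {
  stopifnot(inherits(layout, "genome_layout"), binsize >= 1)
  pieces <- lapply(seq_len(nrow(layout$chromosomes)), function(i) {
    L <- layout$chromosomes$length[i]
    starts <- seq(0, L - 1, by = binsize)
    data.frame(chrom = layout$chromosomes$name[i], start = starts,
               end = pmin(starts + binsize, L), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out$bin <- seq_len(nrow(out))
  attr(out, "binsize") <- as.numeric(binsize)
  attr(out, "layout") <- layout
  class(out) <- c("bin_table", "data.frame")
  out
}

binsize_of <- function(bins) attr(bins, "binsize")

#' Map genomic positions to global bin indices
#'
#' @param bins a [bin_table()].
#' @param chrom,pos vectors of chromosome names and 0-based positions.
#' @return integer vector of global bin indices (NA for positions outside
#'   the table).
#' @export
bin_of <- function(bins, chrom, pos) {
  bs <- binsize_of(bins)
  layout <- attr(bins, "layout")
  ci <- match(chrom, layout$chromosomes$name)
  len <- layout$chromosomes$length[ci]
  off <- chrom_offsets(bins)[ci]
  idx <- off + floor(pos / bs) + 1L
  idx[is.na(ci) | pos < 0 | pos >= len] <- NA_integer_
  as.integer(idx)
}

# first global bin index of each chromosome, minus one
chrom_offsets <- function(bins) {
  r <- rle(bins$chrom)
  setNames(cumsum(c(0L, r$lengths[-length(r$lengths)])), r$values)
}

# global bin index range of one chromosome
chrom_bin_range <- function(bins, chrom) {
  w <- which(bins$chrom == chrom)
  if (!length(w)) stop("chromosome not in bin table: ", chrom)
  range(w)
}

#' Global bin indices overlapping a set of regions
#'
#' @param bins a [bin_table()].
#' @param regions data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return sorted unique integer vector of global bin indices.
#' @export
region_bins <- function(bins, regions) {
  layout <- attr(bins, "layout")
  if (!all(regions$chrom %in% layout$chromosomes$name))
    stop("region on unknown chromosome")
  if (any(regions$start < 0) ||
      any(regions$end > chrom_length(layout, regions$chrom)))
    stop("region outside chromosome bounds")
  idx <- unlist(lapply(seq_len(nrow(regions)), function(i) {
    w <- bins$chrom == regions$chrom[i] & bins$end > regions$start[i] &
      bins$start < regions$end[i]
    bins$bin[w]
  }))
  sort(unique(idx))
}

#' Read a two-column chrom.sizes file
#' @param path text file with columns chromosome name and length.
#' @param ... passed to [genome_layout()] (`centromeres`,
#'   `telomere_margin`).
#' @return a [genome_layout()].
#' @export
read_chrom_sizes <- function(path, ...) {
  x <- utils::read.table(path, header = FALSE, sep = "\t",
                         col.names = c("name", "length"),
                         stringsAsFactors = FALSE)
  genome_layout(stats::setNames(x$length, x$name), ...)
}

#' Read a BED file of regions (first three columns)
#' @param path BED path (0-based half-open, as usual).
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  x <- utils::read.table(path, header = FALSE, sep = "\t",
                         stringsAsFactors = FALSE)
  stats::setNames(x[, 1:3], c("chrom", "start", "end"))
}
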