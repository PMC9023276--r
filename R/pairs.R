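#' Read aligned read pairs from 4DN-style .pairs text
#'
#' Expected columns: readID, chrom1, pos1, chrom2, pos2, strand1, strand2,
#' and optionally mapq1, mapq2 in extra columns. Header lines starting with
#' `#` are skipped; gzip input is accepted. Positions in the file are
#' 1-based and converted to the package's internal 0-based convention.
#'
#' @param path path to a .pairs(.gz) file.
#' @return data.frame with columns `readID`, `chrom1`, `pos1`, `strand1`,
#'   `mapq1`, `chrom2`, `pos2`, `strand2`, `mapq2`.
#' @export
read_pairs <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  x <- utils::read.table(con, header = FALSE, sep = "\t",
                         comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(x) < 7) stop("pairs file needs >= 7 columns")
  out <- data.frame(readID = as.character(x[[1]]),
                    chrom1 = as.character(x[[2]]), pos1 = x[[3]] - 1,
                    chrom2 = as.character(x[[4]]), pos2 = x[[5]] - 1,
                    strand1 = as.character(x[[6]]),
                    strand2 = as.character(x[[7]]),
                    stringsAsFactors = FALSE)
  out$mapq1 <- if (ncol(x) >= 8) as.numeric(x[[8]]) else NA_real_
  out$mapq2 <- if (ncol(x) >= 9) as.numeric(x[[9]]) else NA_real_
  if (any(out$mapq1 < 0, na.rm = TRUE) || any(out$mapq2 < 0, na.rm = TRUE))
    stop("negative MapQ")
  out[, c("readID", "chrom1", "pos1", "strand1", "mapq1",
          "chrom2", "pos2", "strand2", "mapq2")]
}

#' Write read pairs as 4DN-style .pairs text
#' @param pairs data.frame as returned by [read_pairs()].
#' @param path output path (.gz for gzip).
#' @param layout optional [genome_layout()] written into the header.
#' @export
write_pairs <- function(pairs, path, layout = NULL) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines("## pairs format v1.0", con)
  writeLines("#columns: readID chrom1 pos1 chrom2 pos2 strand1 strand2 mapq1 mapq2",
             con)
  if (!is.null(layout))
    writeLines(sprintf("#chromsize: %s %d", layout$chromosomes$name,
                       layout$chromosomes$length), con)
  df <- data.frame(pairs$readID, pairs$chrom1, pairs$pos1 + 1,
                   pairs$chrom2, pairs$pos2 + 1,
                   pairs$strand1, pairs$strand2,
                   ifelse(is.na(pairs$mapq1), ".", pairs$mapq1),
                   ifelse(is.na(pairs$mapq2), ".", pairs$mapq2))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# canonical mate order: (chrom1,pos1) lexicographically <= (chrom2,pos2)
normalize_mate_order <- function(pairs) {
  swap <- pairs$chrom2 < pairs$chrom1 |
    (pairs$chrom2 == pairs$chrom1 & pairs$pos2 < pairs$pos1)
  if (any(swap)) {
    for (cols in list(c("chrom1", "chrom2"), c("pos1", "pos2"),
                      c("strand1", "strand2"), c("mapq1", "mapq2"),
                      c("frag1", "frag2"))) {
      if (!all(cols %in% names(pairs))) next
      tmp <- pairs[[cols[1]]][swap]
      pairs[[cols[1]]][swap] <- pairs[[cols[2]]][swap]
      pairs[[cols[2]]][swap] <- tmp
    }
  }
  pairs
}

#' Filter Hi-C read pairs
#'
#' Applies, in order: PCR-duplicate removal (identical chrom/pos/strand of
#' both mates after canonical mate ordering, first kept), removal of
#' unassigned/repetitive mates (no fragment assignment), low mapping
#' quality (min mate MapQ below `mapq_min`), self-ligation (both mates on
#' the same fragment, any orientation) and undigested products (mates on
#' adjacent fragments with inward orientation: upstream mate `+`,
#' downstream mate `-`). Each pair is counted under the first rule it
#' fails, so the report categories partition the input exactly.
#'
#' @param pairs data.frame of read pairs; run through [assign_fragments()]
#'   first (done automatically when `fragmap` is given and fragment columns
#'   are absent).
#' @param fragmap a [fragment_map()], required if `pairs` lacks
#'   `frag1`/`frag2`.
#' @param mapq_min minimum mate MapQ kept (study default 30; pairs with
#'   MapQ below it were removed).
#' @param exclude optional data.frame of repetitive regions to blacklist
#'   (`chrom`, `start`, `end`, 0-based half-open); a pair with either
#'   mate inside an excluded region is removed under the
#'   repetitive/unassigned rule.
#' @return list with `pairs` (survivors) and `report` (a `filter_report`).
#' @export
filter_pairs <- function(pairs, fragmap = NULL, mapq_min = 30,
                         exclude = NULL) {
  n_in <- nrow(pairs)
  if (!all(c("frag1", "frag2") %in% names(pairs))) {
    if (is.null(fragmap)) stop("fragmap required to assign fragments")
    pairs <- assign_fragments(pairs, fragmap)
  }
  pairs <- normalize_mate_order(pairs)
  key <- paste(pairs$chrom1, pairs$pos1, pairs$strand1,
               pairs$chrom2, pairs$pos2, pairs$strand2, sep = "\r")
  is_dup <- duplicated(key)
  in_exclude <- rep(FALSE, n_in)
  if (!is.null(exclude) && nrow(exclude)) {
    hit <- function(chrom, pos) {
      out <- rep(FALSE, length(pos))
      for (r in seq_len(nrow(exclude)))
        out <- out | (chrom == exclude$chrom[r] &
                        pos >= exclude$start[r] & pos < exclude$end[r])
      out
    }
    in_exclude <- hit(pairs$chrom1, pairs$pos1) |
      hit(pairs$chrom2, pairs$pos2)
  }
  is_unassigned <- !is_dup &
    (is.na(pairs$frag1) | is.na(pairs$frag2) | in_exclude)
  mq <- pmin(ifelse(is.na(pairs$mapq1), Inf, pairs$mapq1),
             ifelse(is.na(pairs$mapq2), Inf, pairs$mapq2))
  is_lowq <- !is_dup & !is_unassigned & mq < mapq_min
  same_chrom <- pairs$chrom1 == pairs$chrom2
  is_self <- !is_dup & !is_unassigned & !is_lowq & same_chrom &
    !is.na(pairs$frag1) & pairs$frag1 == pairs$frag2
  # after mate ordering pos1 <= pos2, so inward means strand1 +, strand2 -
  is_undig <- !is_dup & !is_unassigned & !is_lowq & !is_self & same_chrom &
    !is.na(pairs$frag1) & abs(pairs$frag2 - pairs$frag1) == 1 &
    pairs$strand1 == "+" & pairs$strand2 == "-"
  keep <- !(is_dup | is_unassigned | is_lowq | is_self | is_undig)
  report <- filter_report(input = n_in, duplicate = sum(is_dup),
                          unassigned = sum(is_unassigned),
                          low_mapq = sum(is_lowq),
                          self_ligation = sum(is_self),
                          undigested = sum(is_undig),
                          surviving = sum(keep))
  list(pairs = pairs[keep, , drop = FALSE], report = report)
}

#' Filter bookkeeping record
#'
#' Counts of input pairs and of pairs removed by each rule; the categories
#' always partition the input (asserted at construction).
#'
#' @param input,duplicate,unassigned,low_mapq,self_ligation,undigested,surviving
#'   non-negative counts.
#' @return object of class `filter_report`.
#' @export
filter_report <- function(input, duplicate, unassigned, low_mapq,
                          self_ligation, undigested, surviving) {
  x <- c(input = input, duplicate = duplicate, unassigned = unassigned,
         low_mapq = low_mapq, self_ligation = self_ligation,
         undigested = undigested, surviving = surviving)
  if (any(x < 0)) stop("negative counts in filter report")
  removed <- sum(x[c("duplicate", "unassigned", "low_mapq",
                     "self_ligation", "undigested")])
  if (removed + x[["surviving"]] != x[["input"]])
    stop("filter report does not partition the input")
  structure(as.list(x), class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>\n")
  for (k in c("input", "duplicate", "unassigned", "low_mapq",
              "self_ligation", "undigested", "surviving"))
    cat(sprintf("  %-14s %d\n", k, x[[k]]))
  invisible(x)
}
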