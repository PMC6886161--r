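#' Read genomic intervals from BED-family text files
#'
#' All coordinates are 0-based half-open (UCSC convention). Three column
#' layouts are supported through `kind`:
#' \describe{
#'   \item{`"bed3"`}{`chrom start end` — plain intervals (TADs, peaks, TSS).}
#'   \item{`"bed4-name"`}{`chrom start end name` — labelled intervals
#'     (ChromHMM-style chromatin-state segments).}
#'   \item{`"bedgraph"`}{`chrom start end value` — continuous signal tracks.}
#' }
#'
#' @param path Path to a tab- or space-delimited text file.
#' @param kind One of `"bed3"`, `"bed4-name"`, `"bedgraph"`.
#' @return A tibble with columns `chrom`, `start`, `end` and, depending on
#'   `kind`, `name` (character) or `value` (numeric), sorted by
#'   `(chrom, start)`. Strand is ignored throughout.
#' @export
#' @examples
#' f <- tempfile()
#' writeLines(c("chr6\t120000\t160000", "chr6\t0\t40000"), f)
#' read_bed(f, "bed3")
read_bed <- function(path, kind = c("bed3", "bed4-name", "bedgraph")) {
  kind <- match.arg(kind)
  d <- utils::read.table(path, header = FALSE, sep = "", quote = "",
                         stringsAsFactors = FALSE, comment.char = "#")
  need <- if (kind == "bed3") 3L else 4L
  if (ncol(d) < need) {
    stop("'", kind, "' input needs ", need, " columns, got ", ncol(d))
  }
  out <- tibble::tibble(chrom = as.character(d[[1]]),
                        start = as.numeric(d[[2]]),
                        end = as.numeric(d[[3]]))
  if (anyNA(out$start) || anyNA(out$end)) {
    stop("non-numeric coordinate in ", path)
  }
  bad <- which(out$start >= out$end)
  if (length(bad) > 0) {
    stop("start >= end at line ", bad[1], " of ", path, " (",
         out$start[bad[1]], " >= ", out$end[bad[1]], ")")
  }
  if (any(out$start < 0)) {
    stop("negative coordinate at line ", which(out$start < 0)[1], " of ", path)
  }
  if (kind == "bed4-name") {
    out$name <- as.character(d[[4]])
  } else if (kind == "bedgraph") {
    v <- suppressWarnings(as.numeric(d[[4]]))
    if (anyNA(v)) {
      stop("non-numeric score at line ", which(is.na(v))[1], " of ", path)
    }
    out$value <- v
  }
  dplyr::arrange(out, .data$chrom, .data$start)
}

#' Aggregate genomic intervals onto the beads of a bin index
#'
#' Maps a set of intervals (peaks, TSS, signal segments) onto the `n_beads`
#' fixed-size bins described by `bin_index`, producing one value per bead.
#'
#' Modes:
#' \describe{
#'   \item{`"count"`}{number of intervals whose midpoint falls in the bin.
#'     Each interval is counted exactly once, in the bin containing its
#'     midpoint, so peaks spanning a bin boundary are never double counted.}
#'   \item{`"sum_value"`}{sum of `value` over all intervals overlapping the
#'     bin (an interval contributes its full value to every bin it touches).}
#'   \item{`"mean_value"`}{mean of `value` over overlapping intervals; bins
#'     with no overlapping interval are `NA` (missing, not zero).}
#'   \item{`"any"`}{1 if any interval overlaps the bin, else 0.}
#' }
#'
#' @param intervals Tibble as returned by [read_bed()]; must all be on
#'   `bin_index$chrom`.
#' @param bin_index A [bin_index()].
#' @param n_beads Number of beads.
#' @param mode Aggregation mode, see Details.
#' @return Numeric vector of length `n_beads`.
#' @export
intervals_to_bins <- function(intervals, bin_index, n_beads,
                              mode = c("count", "sum_value", "mean_value",
                                       "any")) {
  mode <- match.arg(mode)
  stopifnot(inherits(bin_index, "bin_index"), n_beads >= 1)
  res <- bin_index$resolution
  off <- bin_index$start_offset
  fill <- if (mode == "mean_value") NA_real_ else 0
  out <- rep(if (mode == "mean_value") 0 else fill, n_beads)
  if (nrow(intervals) == 0) {
    return(if (mode == "mean_value") rep(NA_real_, n_beads) else out)
  }
  if (!all(intervals$chrom == bin_index$chrom)) {
    stop("intervals on chromosome(s) ",
         paste(setdiff(unique(intervals$chrom), bin_index$chrom),
               collapse = ", "),
         " do not match bin index chromosome ", bin_index$chrom)
  }
  if (mode == "count") {
    mid <- (intervals$start + intervals$end) / 2
    b <- floor((mid - off) / res)
    b <- b[b >= 0 & b < n_beads]
    tab <- table(b)
    out[as.integer(names(tab)) + 1L] <- as.numeric(tab)
    return(out)
  }
  # overlap-based modes
  n_over <- rep(0, n_beads)
  acc <- rep(0, n_beads)
  first <- pmax(0, floor((intervals$start - off) / res))
  last <- pmin(n_beads - 1, ceiling((intervals$end - off) / res) - 1)
  for (r in seq_len(nrow(intervals))) {
    if (first[r] > n_beads - 1 || last[r] < 0 || first[r] > last[r]) next
    bins <- seq(first[r], last[r]) + 1L
    if (mode == "any") {
      out[bins] <- 1
    } else {
      acc[bins] <- acc[bins] + intervals$value[r]
      n_over[bins] <- n_over[bins] + 1
    }
  }
  if (mode == "sum_value") return(acc)
  if (mode == "mean_value") {
    return(ifelse(n_over > 0, acc / pmax(n_over, 1), NA_real_))
  }
  out
}
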