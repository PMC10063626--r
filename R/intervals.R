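#' Genomic intervals, peaks and interval arithmetic
#'
#' loopforge represents peaks and loop anchors as plain data frames in
#' 0-based half-open (BED) coordinates: columns `chrom` (character),
#' `start` (integer, inclusive), `end` (integer, exclusive), and for peaks
#' optionally `name` and `signal`. All interval arithmetic is delegated to
#' GenomicRanges; the helpers here take care of the BED (0-based half-open)
#' to IRanges (1-based closed) conversion exactly once.
#'
#' @name intervals
NULL

# Validate an interval data frame; returns it with canonical column types.
validate_intervals <- function(x, what = "interval") {
  if (!is.data.frame(x) || !all(c("chrom", "start", "end") %in% names(x))) {
    stop(sprintf("%s set must be a data.frame with columns chrom, start, end",
                 what), call. = FALSE)
  }
  x$chrom <- as.character(x$chrom)
  x$start <- as.numeric(x$start)
  x$end <- as.numeric(x$end)
  bad <- which(!nzchar(x$chrom) | is.na(x$start) | is.na(x$end) |
                 x$start < 0 | x$start >= x$end)
  if (length(bad)) {
    stop(sprintf("invalid %s at row %d: require chrom non-empty and 0 <= start < end",
                 what, bad[1L]), call. = FALSE)
  }
  x
}

# data.frame (0-based half-open) -> GRanges (1-based closed)
intervals_to_gr <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

# GRanges -> data.frame in BED coordinates
gr_to_intervals <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

#' Find overlapping interval pairs
#'
#' Reports every (query, subject) index pair whose intervals share at least
#' `min_bp` bases on the same chromosome. Coordinates are half-open, so
#' intervals that merely touch (end of one equals start of the other) never
#' overlap.
#'
#' @param query,subject data frames with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param min_bp minimum number of shared bases (default 1).
#' @return data.frame with integer columns `query` and `subject` (row indices).
#' @examples
#' a <- data.frame(chrom = "chr1", start = 100, end = 200)
#' b <- data.frame(chrom = "chr1", start = 150, end = 250)
#' overlap_pairs(a, b)
#' @export
overlap_pairs <- function(query, subject, min_bp = 1L) {
  stopifnot_scalar_number(min_bp, "min_bp", min = 1)
  query <- validate_intervals(query, "query")
  subject <- validate_intervals(subject, "subject")
  # suppressed warning: disjoint chromosome sets are a legitimate query
  hits <- suppressWarnings(GenomicRanges::findOverlaps(
    intervals_to_gr(query), intervals_to_gr(subject),
    minoverlap = as.integer(min_bp)
  ))
  data.frame(
    query = S4Vectors::queryHits(hits),
    subject = S4Vectors::subjectHits(hits)
  )
}

# Logical vector: does each query interval overlap >= 1 subject interval?
overlaps_any <- function(query, subject, min_bp = 1L) {
  if (nrow(subject) == 0L) return(rep(FALSE, nrow(query)))
  hits <- overlap_pairs(query, subject, min_bp = min_bp)
  seq_len(nrow(query)) %in% hits$query
}

#' Merge peak sets into a disjoint union
#'
#' Takes one or more peak sets and collapses overlapping-or-touching
#' intervals on the same chromosome into single spans, the way merged ChIP
#' peak sets are built before being used as a loop-anchor universe. Output
#' is sorted by (chrom, start) and pairwise disjoint.
#'
#' @param ... peak data frames (columns `chrom`, `start`, `end`, extra
#'   columns ignored), or a single list of them.
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @examples
#' merge_peaks(data.frame(chrom = "chr1", start = 100, end = 200),
#'             data.frame(chrom = "chr1", start = 200, end = 300))
#' @export
merge_peaks <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1L]]) && !is.data.frame(sets[[1L]])) {
    sets <- sets[[1L]]
  }
  if (!length(sets)) stop("need at least one peak set", call. = FALSE)
  sets <- lapply(sets, validate_intervals, what = "peak")
  all <- do.call(rbind, lapply(sets, function(s) s[c("chrom", "start", "end")]))
  # reduce() with min.gapwidth = 1 merges overlapping and directly adjacent
  # (touching) intervals, matching `bedtools merge` defaults
  merged <- GenomicRanges::reduce(intervals_to_gr(all), min.gapwidth = 1L)
  merged <- GenomicRanges::sort(merged)
  gr_to_intervals(merged)
}

# midpoint of an interval (numeric; may be *.5)
interval_mid <- function(start, end) (start + end) / 2

# anchor-midpoint distance of loops given as a loops data.frame
loop_distance <- function(loops) {
  interval_mid(loops$start2, loops$end2) - interval_mid(loops$start1, loops$end1)
}
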