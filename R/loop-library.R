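#' Construct a HiChIP loop library
#'
#' A loop library bundles the intra-chromosomal loops of one HiChIP library
#' (anchor pair plus mated paired-end read count) with the library-level
#' total of cis-far unique valid pairs used for strength normalization. The
#' cis-far total comes from upstream Hi-C QC, not from the loop file, and is
#' therefore supplied separately; it is not required to equal or exceed the
#' sum of loop counts.
#'
#' @param loops data.frame with columns `chrom`, `start1`, `end1`, `start2`,
#'   `end2`, `count` and optionally `id`. Coordinates are 0-based half-open.
#'   Anchor pairs are canonicalized so the left anchor starts first; ids are
#'   assigned from coordinates when absent.
#' @param name library name.
#' @param cis_far_total positive number: total cis-far unique valid pairs.
#' @param condition condition label (e.g. "ctrl", "treated").
#' @return object of class `loop_library`: a list with elements `name`,
#'   `condition`, `cis_far_total` and `loops`.
#' @export
loop_library <- function(loops, name = "library", cis_far_total,
                         condition = NA_character_) {
  stopifnot_scalar_number(cis_far_total, "cis_far_total", min = 1)
  need <- c("chrom", "start1", "end1", "start2", "end2", "count")
  if (!is.data.frame(loops) || !all(need %in% names(loops))) {
    stop("'loops' must be a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  loops$chrom <- as.character(loops$chrom)
  for (col in c("start1", "end1", "start2", "end2", "count")) {
    loops[[col]] <- as.numeric(loops[[col]])
  }
  validate_intervals(data.frame(chrom = loops$chrom, start = loops$start1,
                                end = loops$end1), "anchor_a")
  validate_intervals(data.frame(chrom = loops$chrom, start = loops$start2,
                                end = loops$end2), "anchor_b")
  if (any(loops$count < 0 | is.na(loops$count))) {
    stop("loop counts must be nonnegative", call. = FALSE)
  }
  # canonical order: anchor_a strictly left of anchor_b
  swap <- loops$start2 < loops$start1 |
    (loops$start2 == loops$start1 & loops$end2 < loops$end1)
  if (any(swap)) {
    tmp <- loops[swap, c("start1", "end1")]
    loops[swap, c("start1", "end1")] <- loops[swap, c("start2", "end2")]
    loops[swap, c("start2", "end2")] <- tmp
  }
  if (is.null(loops$id) || all(is.na(loops$id))) {
    loops$id <- loop_key(loops)
  }
  loops$id <- as.character(loops$id)
  if (anyDuplicated(loops$id)) {
    stop("loop ids must be unique", call. = FALSE)
  }
  rownames(loops) <- NULL
  structure(
    list(name = name, condition = condition,
         cis_far_total = as.numeric(cis_far_total),
         loops = loops[c("id", "chrom", "start1", "end1", "start2", "end2",
                         "count")]),
    class = "loop_library"
  )
}

# stable coordinate-derived loop identifier, shared across libraries that
# call loops on the same anchor universe
loop_key <- function(loops) {
  sprintf("%s:%d-%d_%d-%d", loops$chrom,
          as.integer(loops$start1), as.integer(loops$end1),
          as.integer(loops$start2), as.integer(loops$end2))
}

#' @export
print.loop_library <- function(x, ...) {
  cat(sprintf("HiChIP loop library '%s'%s\n", x$name,
              if (is.na(x$condition)) "" else sprintf(" [%s]", x$condition)))
  cat(sprintf("  %d intra-chromosomal loops on %d chromosome(s)\n",
              nrow(x$loops), length(unique(x$loops$chrom))))
  cat(sprintf("  total mated-PE reads in loops: %.0f\n", sum(x$loops$count)))
  cat(sprintf("  cis-far unique valid pairs: %.3g\n", x$cis_far_total))
  invisible(x)
}

#' Extract the anchor intervals of a loop library
#'
#' @param library a [loop_library()].
#' @param which which anchor side to return: "both" (default), "a" (left)
#'   or "b" (right).
#' @param unique_only drop duplicate intervals (default TRUE).
#' @return interval data.frame with columns `chrom`, `start`, `end`.
#' @export
library_anchors <- function(library, which = c("both", "a", "b"),
                            unique_only = TRUE) {
  which <- match.arg(which)
  l <- library$loops
  a <- data.frame(chrom = l$chrom, start = l$start1, end = l$end1,
                  stringsAsFactors = FALSE)
  b <- data.frame(chrom = l$chrom, start = l$start2, end = l$end2,
                  stringsAsFactors = FALSE)
  out <- switch(which, a = a, b = b, both = rbind(a, b))
  if (unique_only) out <- unique(out)
  rownames(out) <- NULL
  out
}
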