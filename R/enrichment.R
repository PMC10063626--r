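#' Fraction of anchors overlapping a peak set
#'
#' @param anchors interval data frame (non-empty).
#' @param peaks peak data frame.
#' @return fraction in [0, 1] of anchors overlapping at least one peak by
#'   at least 1 bp.
#' @export
overlap_ratio <- function(anchors, peaks) {
  anchors <- validate_intervals(anchors, "anchor")
  if (!nrow(anchors)) stop("anchor set is empty", call. = FALSE)
  mean(overlaps_any(anchors, peaks))
}

#' Observed-vs-expected enrichment of peak overlap at an anchor set
#'
#' Tests whether a target anchor set (e.g. anchors of dysregulated loops)
#' overlaps a TF peak set more often than size-matched random anchor sets
#' drawn from the full anchor universe of the same HiChIP mark. `B` draws
#' of `nrow(target)` anchors are sampled without replacement from the
#' universe; the observed overlap fraction is divided by the mean of the
#' null fractions to give O/E. Significance is reported two ways: a
#' two-sided one-sample Student's t-test of the null fractions against the
#' observed value (`p_t`), and an add-one-smoothed empirical upper-tail
#' p-value (`p_emp = (1 + #\{null >= observed\}) / (B + 1)`), which is the
#' more conservative of the two for skewed nulls.
#'
#' @param target interval data frame of target anchors.
#' @param universe interval data frame of all anchors of the mark;
#'   must have at least as many rows as `target`.
#' @param peaks TF peak data frame.
#' @param B number of random draws (default 500).
#' @param seed integer seed; the draw sequence is fully determined by it.
#' @return object of class `loop_enrichment`: list with `n_target`,
#'   `observed_ratio`, `null_ratios` (length B), `expected_ratio`, `oe`,
#'   `p_t`, `p_emp`, `B`, `seed`.
#' @export
oe_enrichment <- function(target, universe, peaks, B = 500, seed = 1L) {
  stopifnot_scalar_number(B, "B", min = 1)
  target <- validate_intervals(target, "target anchor")
  universe <- validate_intervals(universe, "universe anchor")
  if (nrow(target) > nrow(universe)) {
    stop("target set larger than universe", call. = FALSE)
  }
  observed <- overlap_ratio(target, peaks)
  hit <- overlaps_any(universe, peaks)  # per-universe-anchor indicator
  n_t <- nrow(target)
  null_ratios <- with_seed(seed, {
    vapply(seq_len(B), function(i) mean(hit[sample.int(nrow(universe), n_t)]),
           numeric(1))
  })
  expected <- mean(null_ratios)
  p_t <- if (stats::sd(null_ratios) > 0) {
    stats::t.test(null_ratios, mu = observed)$p.value
  } else {
    as.numeric(null_ratios[1L] == observed)  # degenerate null: 1 iff equal
  }
  structure(
    list(n_target = n_t, observed_ratio = observed,
         null_ratios = null_ratios, expected_ratio = expected,
         oe = if (expected > 0) observed / expected else Inf,
         p_t = p_t,
         p_emp = (1 + sum(null_ratios >= observed)) / (B + 1),
         B = B, seed = seed),
    class = "loop_enrichment"
  )
}

#' @export
print.loop_enrichment <- function(x, ...) {
  cat("Anchor overlap enrichment (observed vs expected)\n")
  cat(sprintf("  target anchors: %d; observed overlap: %.3f\n",
              x$n_target, x$observed_ratio))
  cat(sprintf("  expected (mean of %d size-matched draws): %.3f\n",
              x$B, x$expected_ratio))
  cat(sprintf("  O/E = %.2f; t-test p = %.3g; empirical p = %.3g\n",
              x$oe, x$p_t, x$p_emp))
  invisible(x)
}
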