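#' Anchor-length-corrected loop strength
#'
#' HiChIP anchors vary in width, and wider anchor pairs accumulate more
#' mated paired-end reads for the same underlying contact. The corrected
#' strength rescales each loop's read count to a common reference span:
#' \deqn{m = \mathrm{round}\left(c \cdot \frac{s_{ref}}{w_a + w_b}\right)}
#' where \eqn{c} is the raw count, \eqn{w_a + w_b} the summed anchor widths
#' and \eqn{s_{ref}} the reference span (by default the library-wide median
#' of \eqn{w_a + w_b}). Rounding is half-up so that m stays integer-valued
#' for the binomial model; m is 0 only when the count is 0. Libraries whose
#' anchors all have the reference width are left unchanged.
#'
#' @param count raw mated-PE read count(s).
#' @param width_a,width_b anchor widths in bp.
#' @param median_anchor_span reference span in bp (positive).
#' @return corrected strength m (integer-valued numeric, vectorized).
#' @export
correct_strength <- function(count, width_a, width_b, median_anchor_span) {
  stopifnot_scalar_number(median_anchor_span, "median_anchor_span", min = 1)
  if (any(count < 0)) stop("count must be nonnegative", call. = FALSE)
  if (any(width_a <= 0 | width_b <= 0)) {
    stop("anchor widths must be positive", call. = FALSE)
  }
  m <- round_half_up(count * median_anchor_span / (width_a + width_b))
  # a nonzero count never rounds down to zero strength
  pmax(m, as.numeric(count > 0))
}

#' Per-chromosome anchor-universe statistics
#'
#' Estimates, per chromosome, the size of the full loop-anchor universe.
#' Observed anchors are the distinct anchor intervals that appear in at
#' least one loop; potential anchors are peak-bearing regions with no mated
#' reads. Because one anchor can span several ChIP peaks, the universe is
#' estimated by proportionality: the observed-anchor fraction of all
#' possible anchors is taken to equal the fraction of ChIP peaks that fall
#' inside observed anchors, giving
#' \deqn{N_{possible} = \mathrm{round}\left(\frac{N_{obs} \cdot N_{peaks}}{N_{peaks\ in\ obs}}\right).}
#'
#' @param library a [loop_library()].
#' @param peaks ChIP peak data frame matched to the HiChIP antibody.
#' @param rounding "half_up" (default) or "floor" for the universe estimate.
#' @return data.frame with one row per chromosome carrying
#'   `n_observed_anchors`, `n_total_peaks`, `n_peaks_in_observed`,
#'   `n_possible_anchors` and `n_possible_loops_chrom`.
#' @export
tally_chrom_stats <- function(library, peaks,
                              rounding = c("half_up", "floor")) {
  rounding <- match.arg(rounding)
  peaks <- validate_intervals(peaks, "peak")
  chroms <- sort(unique(library$loops$chrom))
  rows <- lapply(chroms, function(ch) {
    anchors <- unique(library_anchors(
      list(loops = library$loops[library$loops$chrom == ch, , drop = FALSE])))
    pk <- peaks[peaks$chrom == ch, , drop = FALSE]
    n_obs <- nrow(anchors)
    n_peaks <- nrow(pk)
    n_in <- if (n_peaks) sum(overlaps_any(pk, anchors)) else 0L
    if (n_obs > 0L && n_in == 0L) {
      stop(sprintf("chromosome %s: anchors lack matched ChIP peaks", ch),
           call. = FALSE)
    }
    est <- n_obs * n_peaks / n_in
    n_poss <- if (rounding == "half_up") round_half_up(est) else floor(est)
    data.frame(chrom = ch, n_observed_anchors = n_obs, n_total_peaks = n_peaks,
               n_peaks_in_observed = n_in, n_possible_anchors = n_poss,
               n_possible_loops_chrom = choose(n_poss, 2),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Genome-wide loop-model parameters
#'
#' Sums the per-chromosome anchor universes into the genome-wide number of
#' possible intra-chromosomal loops \eqn{N = \sum_i \binom{N_i}{2}} and the
#' per-loop read probability \eqn{p = 1/N} of the uniform binomial null.
#'
#' @param stats output of [tally_chrom_stats()].
#' @return list with `n_possible_loops` and `p_loop`.
#' @export
possible_loops <- function(stats) {
  n <- sum(stats$n_possible_loops_chrom)
  if (n <= 0) {
    stop("no possible loops: every chromosome contributes fewer than 2 anchors",
         call. = FALSE)
  }
  list(n_possible_loops = n, p_loop = 1 / n)
}

#' Upper-tail binomial loop p-value
#'
#' Probability of observing at least `m` of `n` total corrected reads on
#' one specific loop when each read lands on any of the possible loops
#' uniformly (success probability `p`). Computed via the binomial survival
#' function; m = 0 returns 1.
#'
#' @param m corrected loop strength (0 <= m <= n), vectorized.
#' @param n total corrected loop strength of the library.
#' @param p per-loop read probability in (0, 1].
#' @return upper-tail probability P(X >= m).
#' @export
loop_pvalue <- function(m, n, p) {
  stopifnot_scalar_number(n, "n", min = 0)
  stopifnot_scalar_number(p, "p", min = .Machine$double.xmin, max = 1)
  if (any(m < 0) || any(m > n)) stop("require 0 <= m <= n", call. = FALSE)
  stats::pbinom(m - 1, size = n, prob = p, lower.tail = FALSE)
}

#' Bonferroni-Holm step-down adjustment
#'
#' Family-wise error-rate correction of loop p-values: sort ascending,
#' multiply the i-th smallest by (k - i + 1), and enforce monotonicity by a
#' running maximum, capping at 1. Tied p-values receive equal adjusted
#' values. Input order is preserved.
#'
#' @param pvals numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same order as input.
#' @export
holm_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "holm")
}

#' Call significant HiChIP loops by the binomial anchor-pair model
#'
#' The central fitting function. Loops closer than `min_distance`
#' (anchor-midpoint to anchor-midpoint) are removed first, mirroring the
#' cis-far (>10 kb) definition of informative di-tags. Each retained loop's
#' count is corrected for anchor length ([correct_strength()]); the
#' per-chromosome anchor universe is estimated from the matched ChIP peaks
#' ([tally_chrom_stats()]); reads are modeled as falling uniformly on the
#' \eqn{N = \sum \binom{N_i}{2}} possible intra-chromosomal anchor pairs, so
#' a loop of corrected strength m out of the library total n has upper-tail
#' binomial p-value P(X >= m | n, p = 1/N). P-values are Holm-adjusted
#' across all retained loops and loops with adjusted p below `alpha` are
#' flagged significant.
#'
#' @param library a [loop_library()].
#' @param peaks ChIP peak data frame matched to the HiChIP antibody.
#' @param alpha significance level on the adjusted p-value (default 0.05).
#' @param min_distance loops at anchor-midpoint distance <= this are
#'   excluded (default 10000 bp, the cis-far floor).
#' @param correction anchor-length correction strategy: "median_span"
#'   (default) rescales to the library-median summed anchor span; "none"
#'   uses raw counts.
#' @param adjust multiple-testing method: "holm" (default, family-wise) or
#'   "BH" (false discovery rate, for sensitivity analyses).
#' @param rounding rounding of the anchor-universe estimate ("half_up" or
#'   "floor").
#' @return object of class `loop_call`: list with `results` (loop table
#'   plus `m`, `p_raw`, `p_adj`, `significant`), `params` (model audit
#'   record), `chrom_stats` and `n_filtered`.
#' @examples
#' sim <- simulate_hichip(sim_config(n_chrom = 1, n_peaks_per_chrom = 15))
#' fit <- call_loops(sim$libraries$k27_a, sim$peaks$k27)
#' summary(fit)
#' @export
call_loops <- function(library, peaks, alpha = 0.05, min_distance = 10000,
                       correction = c("median_span", "none"),
                       adjust = c("holm", "BH"),
                       rounding = c("half_up", "floor")) {
  correction <- match.arg(correction)
  adjust <- match.arg(adjust)
  rounding <- match.arg(rounding)
  stopifnot_scalar_number(alpha, "alpha", min = 0, max = 1)
  if (!inherits(library, "loop_library")) {
    stop("'library' must be a loop_library", call. = FALSE)
  }
  if (!nrow(library$loops)) stop("library has no loops", call. = FALSE)

  loops <- library$loops
  dist <- loop_distance(loops)
  retained <- loops[dist > min_distance, , drop = FALSE]
  n_filtered <- nrow(loops) - nrow(retained)
  if (!nrow(retained)) {
    stop("no loops beyond min_distance; nothing to model", call. = FALSE)
  }

  w_a <- retained$end1 - retained$start1
  w_b <- retained$end2 - retained$start2
  span <- max(1, round_half_up(stats::median(w_a + w_b)))
  m <- if (correction == "median_span") {
    correct_strength(retained$count, w_a, w_b, span)
  } else {
    retained$count
  }
  n_total <- sum(m)

  sub <- library
  sub$loops <- retained
  chrom_stats <- tally_chrom_stats(sub, peaks, rounding = rounding)
  model <- possible_loops(chrom_stats)

  p_raw <- if (n_total > 0) {
    loop_pvalue(m, n_total, model$p_loop)
  } else {
    rep(1, nrow(retained))
  }
  p_adj <- if (adjust == "holm") holm_adjust(p_raw) else stats::p.adjust(p_raw, "BH")
  # strict threshold, except the degenerate alpha = 1 where p_adj is capped
  # at 1 and everything passes by convention
  significant <- if (alpha >= 1) rep(TRUE, length(p_adj)) else p_adj < alpha

  results <- cbind(
    retained,
    data.frame(distance = loop_distance(retained), m = m, p_raw = p_raw,
               p_adj = p_adj, significant = significant)
  )
  rownames(results) <- NULL

  structure(
    list(
      results = results,
      params = list(
        n_possible_loops = model$n_possible_loops,
        p_loop = model$p_loop,
        n_total_strength = n_total,
        median_anchor_span = span,
        alpha = alpha, min_distance = min_distance,
        correction = correction, adjust = adjust, rounding = rounding
      ),
      chrom_stats = chrom_stats,
      n_filtered = n_filtered,
      library_name = library$name
    ),
    class = "loop_call"
  )
}

#' @export
print.loop_call <- function(x, ...) {
  cat(sprintf("Binomial loop-significance fit for '%s'\n", x$library_name))
  cat(sprintf("  %d loops tested (%d removed below %g bp)\n",
              nrow(x$results), x$n_filtered, x$params$min_distance))
  cat(sprintf("  possible loops N = %.0f, p = %.3g, total strength n = %.0f\n",
              x$params$n_possible_loops, x$params$p_loop,
              x$params$n_total_strength))
  cat(sprintf("  significant loops (%s-adjusted p < %g): %d\n",
              x$params$adjust, x$params$alpha, sum(x$results$significant)))
  invisible(x)
}

#' @export
summary.loop_call <- function(object, ...) {
  res <- object$results
  out <- list(
    library = object$library_name,
    n_tested = nrow(res),
    n_filtered = object$n_filtered,
    n_significant = sum(res$significant),
    params = object$params,
    chrom_stats = object$chrom_stats,
    strength_quartiles = stats::quantile(res$m, c(0, .25, .5, .75, 1))
  )
  class(out) <- "summary.loop_call"
  out
}

#' @export
print.summary.loop_call <- function(x, ...) {
  cat(sprintf("Loop-call summary for '%s'\n", x$library))
  cat(sprintf("  tested %d, filtered %d, significant %d\n",
              x$n_tested, x$n_filtered, x$n_significant))
  cat("  corrected strength quartiles:\n")
  print(x$strength_quartiles)
  cat("  per-chromosome anchor universe:\n")
  print(x$chrom_stats, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.loop_call <- function(x, ...) x$results

#' Extract the ids of significant loops
#'
#' @param fit a `loop_call` object.
#' @return character vector of significant loop ids.
#' @export
significant_loops <- function(fit) {
  stopifnot(inherits(fit, "loop_call"))
  fit$results$id[fit$results$significant]
}

#' Write a loop-call table and JSON audit record
#'
#' Emits the BEDPE-plus-statistics table (tab-separated, with header) and,
#' alongside it, a JSON audit record of the fitted model parameters and
#' per-chromosome anchor statistics.
#'
#' @param fit a `loop_call` object.
#' @param path output path for the table; the audit record is written to
#'   `<path>.audit.json`.
#' @export
write_loop_calls <- function(fit, path) {
  stopifnot(inherits(fit, "loop_call"))
  res <- fit$results
  out <- data.frame(
    chrom1 = res$chrom, start1 = as.integer(res$start1), end1 = as.integer(res$end1),
    chrom2 = res$chrom, start2 = as.integer(res$start2), end2 = as.integer(res$end2),
    name = res$id, count = res$count, m = res$m,
    p_raw = res$p_raw, p_adj_holm = res$p_adj, significant = res$significant
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  audit <- list(params = fit$params, chrom_stats = fit$chrom_stats,
                n_filtered = fit$n_filtered)
  jsonlite::write_json(audit, paste0(path, ".audit.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(path)
}
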