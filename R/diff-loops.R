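#' Two-condition differential looping
#'
#' Tests each loop for a change in contact frequency between two HiChIP
#' libraries. Loops are matched across libraries by both-anchor overlap
#' ([match_loops()]); a loop absent from one library enters with count 0.
#' Loops whose summed count is below `min_total` are reported untested
#' ("ns"). Each tested loop is evaluated by a two-sided Fisher exact test
#' on the 2x2 table of loop count versus the remainder of the library's
#' cis-far valid pairs, i.e. a test of equal per-read loop rates between
#' libraries of (possibly) different depths. P-values are
#' Benjamini-Hochberg corrected across tested loops. A loop is called
#' "up" (stronger in B) when q < `alpha` and the depth-normalized fold
#' change exceeds `fold_threshold`; "down" symmetrically.
#'
#' The log2 fold change uses depth-normalized strengths with a pseudocount
#' rescaled like the counts:
#' log2((norm_b + pc_b) / (norm_a + pc_a)) with pc_x = pseudocount * scale
#' / cis_far_total_x.
#'
#' @param lib_a,lib_b [loop_library()] objects for the two conditions.
#' @param alpha BH-adjusted significance level (default 0.05).
#' @param min_total minimum summed raw count for a loop to be tested
#'   (default 5).
#' @param pseudocount pseudocount on the raw-count scale (default 0.5).
#' @param fold_threshold minimum fold change (linear scale) for a
#'   directional call (default 1.5).
#' @param scale normalization scale (default 1e8).
#' @return object of class `loop_diff`: list with `results` (per-loop
#'   table: ids, counts, normalized strengths, log2fc, p_raw, q_bh,
#'   direction, coordinates) and the comparison metadata.
#' @examples
#' sim <- simulate_hichip(sim_config(n_chrom = 1, n_peaks_per_chrom = 15))
#' d <- diff_loops(sim$libraries$k27_a, sim$libraries$k27_b)
#' table(d$results$direction)
#' @export
diff_loops <- function(lib_a, lib_b, alpha = 0.05, min_total = 5,
                       pseudocount = 0.5, fold_threshold = 1.5,
                       scale = 1e8) {
  if (identical(lib_a, lib_b)) {
    stop("lib_a and lib_b are the same library object (self-comparison)",
         call. = FALSE)
  }
  stopifnot_scalar_number(alpha, "alpha", min = 0, max = 1)
  la <- lib_a$loops; lb <- lib_b$loops
  pairs <- matched_loop_pairs(la, lb)

  # union loop set: every A loop (with the summed counts of its B matches),
  # plus B loops matched by no A loop
  b_counts <- stats::setNames(lb$count, lb$id)
  count_b_for_a <- rep(0, nrow(la))
  if (nrow(pairs)) {
    sums <- tapply(b_counts[pairs$id_b], pairs$id_a, sum)
    idx <- match(names(sums), la$id)
    count_b_for_a[idx] <- as.numeric(sums)
  }
  only_b <- !(lb$id %in% pairs$id_b)
  res <- rbind(
    data.frame(loop_id = la$id, chrom = la$chrom,
               start1 = la$start1, end1 = la$end1,
               start2 = la$start2, end2 = la$end2,
               count_a = la$count, count_b = count_b_for_a,
               stringsAsFactors = FALSE),
    data.frame(loop_id = lb$id[only_b], chrom = lb$chrom[only_b],
               start1 = lb$start1[only_b], end1 = lb$end1[only_b],
               start2 = lb$start2[only_b], end2 = lb$end2[only_b],
               count_a = rep(0, sum(only_b)), count_b = lb$count[only_b],
               stringsAsFactors = FALSE)
  )

  tot_a <- lib_a$cis_far_total
  tot_b <- lib_b$cis_far_total
  res$norm_a <- res$count_a / tot_a * scale
  res$norm_b <- res$count_b / tot_b * scale
  pc_a <- pseudocount / tot_a * scale
  pc_b <- pseudocount / tot_b * scale
  res$log2fc <- log2((res$norm_b + pc_b) / (res$norm_a + pc_a))

  tested <- res$count_a + res$count_b >= min_total
  res$p_raw <- NA_real_
  if (any(tested)) {
    res$p_raw[tested] <- mapply(function(ca, cb) {
      stats::fisher.test(matrix(c(ca, tot_a - ca, cb, tot_b - cb), 2L, 2L))$p.value
    }, res$count_a[tested], res$count_b[tested])
  }
  res$q_bh <- NA_real_
  res$q_bh[tested] <- stats::p.adjust(res$p_raw[tested], method = "BH")

  lfc_min <- log2(fold_threshold)
  res$direction <- "ns"
  sig <- tested & !is.na(res$q_bh) & res$q_bh < alpha & abs(res$log2fc) > lfc_min
  res$direction[sig & res$log2fc > 0] <- "up"
  res$direction[sig & res$log2fc < 0] <- "down"
  rownames(res) <- NULL

  structure(
    list(results = res,
         lib_a = lib_a$name, lib_b = lib_b$name,
         cis_far_total_a = tot_a, cis_far_total_b = tot_b,
         alpha = alpha, min_total = min_total, pseudocount = pseudocount,
         fold_threshold = fold_threshold, scale = scale),
    class = "loop_diff"
  )
}

#' @export
print.loop_diff <- function(x, ...) {
  tab <- table(factor(x$results$direction, levels = c("up", "down", "ns")))
  cat(sprintf("Differential looping: '%s' vs '%s'\n", x$lib_b, x$lib_a))
  cat(sprintf("  %d loops in union set, %d tested\n",
              nrow(x$results), sum(!is.na(x$results$p_raw))))
  cat(sprintf("  up %d, down %d (q < %g and |fold| > %g)\n",
              tab[["up"]], tab[["down"]], x$alpha, x$fold_threshold))
  invisible(x)
}

#' @export
as.data.frame.loop_diff <- function(x, ...) x$results

#' Significantly changed loops per chromosome
#'
#' @param diff a `loop_diff` object.
#' @return data.frame with columns `chrom`, `n_up`, `n_down`; one row per
#'   chromosome carrying at least one significant loop.
#' @export
classify_diff_by_chromosome <- function(diff) {
  res <- diff$results[diff$results$direction != "ns", , drop = FALSE]
  if (!nrow(res)) {
    return(data.frame(chrom = character(), n_up = integer(),
                      n_down = integer()))
  }
  tab <- table(res$chrom, factor(res$direction, levels = c("up", "down")))
  data.frame(chrom = rownames(tab), n_up = as.integer(tab[, "up"]),
             n_down = as.integer(tab[, "down"]), row.names = NULL)
}

#' Loop-length distribution of changed loops
#'
#' Histograms the anchor-midpoint distances of up- and downregulated loops
#' over the given bin edges (lower-inclusive, upper-exclusive).
#'
#' @param diff a `loop_diff` object.
#' @param breaks monotone increasing numeric vector of bin edges.
#' @return list with `breaks` and integer matrices rows = bins: columns
#'   `up`, `down`.
#' @export
loop_length_distribution <- function(diff, breaks) {
  if (is.unsorted(breaks, strictly = TRUE)) {
    stop("breaks must be strictly increasing", call. = FALSE)
  }
  res <- diff$results
  dist <- interval_mid(res$start2, res$end2) - interval_mid(res$start1, res$end1)
  bin_counts <- function(d) {
    if (!length(d)) return(integer(length(breaks) - 1L))
    idx <- findInterval(d, breaks, rightmost.closed = FALSE)
    idx[idx == 0L | idx == length(breaks)] <- NA_integer_  # outside range
    tabulate(idx, nbins = length(breaks) - 1L)
  }
  counts <- cbind(up = bin_counts(dist[res$direction == "up"]),
                  down = bin_counts(dist[res$direction == "down"]))
  list(breaks = breaks, counts = counts)
}
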