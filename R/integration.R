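#' Classify TF-binding / expression trend pairs
#'
#' Labels each (binding log2 fold change, expression log2 fold change) pair
#' as "consistent" (same sign, both absolute fold changes above
#' `threshold_fold`), "opposite" (opposite signs, both above), or
#' "neither".
#'
#' @param binding_log2fc,expr_log2fc numeric vectors (log2 scale).
#' @param threshold_fold linear-scale fold-change threshold (default 1.5).
#' @return character vector of labels.
#' @export
classify_trend_pairs <- function(binding_log2fc, expr_log2fc,
                                 threshold_fold = 1.5) {
  if (length(binding_log2fc) != length(expr_log2fc)) {
    stop("fold-change vectors must have equal length", call. = FALSE)
  }
  thr <- log2(threshold_fold)
  big <- abs(binding_log2fc) > thr & abs(expr_log2fc) > thr
  same <- sign(binding_log2fc) == sign(expr_log2fc)
  out <- rep("neither", length(binding_log2fc))
  out[big & same] <- "consistent"
  out[big & !same] <- "opposite"
  out
}

#' Chi-square test of a 2x2 contingency table
#'
#' Pearson chi-square with one degree of freedom,
#' \eqn{\chi^2 = \sum (\max(0, |O - E| - c))^2 / E} with continuity
#' correction c = 0.5 (Yates, default) or c = 0. Without the correction
#' this equals the closed form N(ad-bc)^2 / ((a+b)(c+d)(a+c)(b+d)).
#'
#' @param table 2x2 matrix of nonnegative counts; no marginal may be zero.
#' @param yates apply the Yates continuity correction (default TRUE).
#' @return list of class `chi2_2x2` with `table`, `chi2`, `df` (1),
#'   `yates`, `p`.
#' @examples
#' chi2_2x2(matrix(c(343, 134, 333, 87), 2, 2))  # p ~ 0.013
#' @export
chi2_2x2 <- function(table, yates = TRUE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("need a 2x2 table", call. = FALSE)
  if (any(table < 0) || any(is.na(table))) {
    stop("cell counts must be nonnegative", call. = FALSE)
  }
  rs <- rowSums(table); cs <- colSums(table)
  if (any(rs == 0) || any(cs == 0)) {
    stop("zero marginal in contingency table", call. = FALSE)
  }
  expected <- outer(rs, cs) / sum(table)
  c0 <- if (yates) 0.5 else 0
  dev <- pmax(0, abs(table - expected) - c0)
  chi2 <- sum(dev^2 / expected)
  structure(
    list(table = table, chi2 = chi2, df = 1L, yates = yates,
         p = stats::pchisq(chi2, df = 1L, lower.tail = FALSE)),
    class = "chi2_2x2"
  )
}

#' @export
print.chi2_2x2 <- function(x, ...) {
  cat(sprintf("Chi-square test (df = 1%s): chi2 = %.4g, p = %.4g\n",
              if (x$yates) ", Yates-corrected" else "", x$chi2, x$p))
  invisible(x)
}

#' Find CTCF loops crossing H3K27ac loops
#'
#' Detects the insulating geometry in which a CTCF loop interleaves an
#' enhancer-promoter (H3K27ac) contact: exactly one of the CTCF loop's two
#' anchor midpoints lies strictly inside the open interval between the
#' H3K27ac loop's anchor midpoints. Nested and disjoint configurations are
#' not crossings under the default mode; `mode = "nested_inclusive"` also
#' accepts CTCF loops fully nested inside the H3K27ac span.
#'
#' @param k27_loops data.frame of H3K27ac loops (columns `id`/`loop_id`,
#'   `chrom`, `start1`, `end1`, `start2`, `end2`), e.g. the down-regulated
#'   rows of a [diff_loops()] result.
#' @param ctcf_loops data.frame of CTCF loops, same columns.
#' @param mode "interleaved" (default) or "nested_inclusive".
#' @return data.frame with columns `k27_loop_id`, `ctcf_loop_id`, one row
#'   per crossing pair.
#' @export
find_crossings <- function(k27_loops, ctcf_loops,
                           mode = c("interleaved", "nested_inclusive")) {
  mode <- match.arg(mode)
  idcol <- function(df) df[["id"]] %||% df[["loop_id"]]
  k_id <- idcol(k27_loops); c_id <- idcol(ctcf_loops)
  if (is.null(k_id) || is.null(c_id)) {
    stop("loop tables need an 'id' or 'loop_id' column", call. = FALSE)
  }
  out <- list()
  for (ch in intersect(unique(k27_loops$chrom), unique(ctcf_loops$chrom))) {
    k <- k27_loops[k27_loops$chrom == ch, , drop = FALSE]
    c_ <- ctcf_loops[ctcf_loops$chrom == ch, , drop = FALSE]
    k_a <- interval_mid(k$start1, k$end1); k_b <- interval_mid(k$start2, k$end2)
    c_a <- interval_mid(c_$start1, c_$end1); c_b <- interval_mid(c_$start2, c_$end2)
    for (i in seq_len(nrow(k))) {
      in_a <- c_a > k_a[i] & c_a < k_b[i]
      in_b <- c_b > k_a[i] & c_b < k_b[i]
      cross <- if (mode == "interleaved") xor(in_a, in_b) else (in_a | in_b)
      if (any(cross)) {
        out[[length(out) + 1L]] <- data.frame(
          k27_loop_id = idcol(k)[i], ctcf_loop_id = idcol(c_)[cross],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(k27_loop_id = character(), ctcf_loop_id = character()))
  }
  do.call(rbind, out)
}

#' Genes at the promoters of crossed H3K27ac loops
#'
#' Takes the crossing table from [find_crossings()] and maps each crossed
#' H3K27ac loop to the genes whose TSS falls within `window` bp of either
#' of its anchors; returns the union as a set.
#'
#' @param crossings data.frame from [find_crossings()].
#' @param k27_loops the H3K27ac loop table the crossings refer to.
#' @param genes gene-model data frame.
#' @param window TSS window in bp (default 3000).
#' @return character vector of unique gene ids.
#' @export
crossed_loop_genes <- function(crossings, k27_loops, genes, window = 3000) {
  if (!nrow(crossings)) return(character())
  idcol <- k27_loops[["id"]] %||% k27_loops[["loop_id"]]
  crossed <- k27_loops[idcol %in% unique(crossings$k27_loop_id), , drop = FALSE]
  anchors <- rbind(
    data.frame(chrom = crossed$chrom, start = crossed$start1, end = crossed$end1),
    data.frame(chrom = crossed$chrom, start = crossed$start2, end = crossed$end2)
  )
  hits <- annotate_anchor_genes(anchors, genes, window = window)
  unique(unlist(hits))
}

#' Contingency test of crossed genes against differential expression
#'
#' Builds the 2x2 table of {downregulated, upregulated} genes x {promoter
#' in the crossed set, not} and applies the Yates-corrected chi-square
#' test, asking whether genes whose enhancer-promoter loops are crossed by
#' gained CTCF loops are preferentially downregulated.
#'
#' @param crossed_genes character vector of crossed-promoter gene ids.
#' @param up_genes,down_genes disjoint character vectors of up- and
#'   downregulated gene ids.
#' @return a `chi2_2x2` result with the table oriented rows = (down, up),
#'   columns = (crossed, not crossed).
#' @export
crossover_contingency <- function(crossed_genes, up_genes, down_genes) {
  if (length(intersect(up_genes, down_genes))) {
    stop("up and down gene sets overlap", call. = FALSE)
  }
  tab <- matrix(
    c(sum(down_genes %in% crossed_genes), sum(!(down_genes %in% crossed_genes)),
      sum(up_genes %in% crossed_genes), sum(!(up_genes %in% crossed_genes))),
    nrow = 2L, byrow = TRUE,
    dimnames = list(c("down", "up"), c("crossed", "not_crossed"))
  )
  chi2_2x2(tab, yates = TRUE)
}

#' Per-sample gene-set z-scores
#'
#' Standardizes each gene's expression across samples (sample mean,
#' sample standard deviation with n-1 denominator), drops constant genes,
#' and averages the z-scores of the set genes per sample. Scores have mean
#' ~0 across samples by construction.
#'
#' @param expr numeric gene x sample matrix with gene ids as rownames.
#' @param gene_set character vector of gene ids; genes missing from `expr`
#'   are dropped with a warning.
#' @return data.frame with columns `sample_id`, `score`.
#' @export
geneset_zscore <- function(expr, gene_set) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 2L) stop("need at least 2 samples", call. = FALSE)
  missing <- setdiff(gene_set, rownames(expr))
  if (length(missing)) {
    warning(sprintf("%d gene(s) in set absent from expression matrix",
                    length(missing)))
  }
  sub <- expr[intersect(gene_set, rownames(expr)), , drop = FALSE]
  sds <- apply(sub, 1L, stats::sd)
  sub <- sub[sds > 0, , drop = FALSE]
  if (!nrow(sub)) stop("no scorable genes (all absent or constant)", call. = FALSE)
  z <- t(scale(t(sub)))  # per-gene z across samples, sd with n-1
  data.frame(sample_id = colnames(expr), score = colMeans(z),
             row.names = NULL)
}
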