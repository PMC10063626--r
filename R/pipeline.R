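#' Run the full loop-analysis pipeline on a data bundle
#'
#' Chains every stage on a simulated or loaded input bundle: significant
#' loop calling per library, loop annotation, two differential comparisons
#' (H3K27ac and CTCF, condition B vs A), TF-binding enrichment at the
#' anchors of upregulated CTCF loops against the full CTCF anchor
#' universe, the crossover (insulation) analysis of downregulated H3K27ac
#' loops against upregulated CTCF loops, the crossed-gene contingency test
#' against the up/down gene sets, and per-sample gene-set z-scores of the
#' down genes. A JSON manifest of parameters, seed and per-stage row
#' counts is written when `out_dir` is given, together with the per-stage
#' result tables.
#'
#' The pipeline is a pure function of (bundle, parameters, seed): rerunning
#' with the same inputs reproduces every output.
#'
#' @param bundle a `sim_bundle` from [simulate_hichip()], or an equivalent
#'   list with `peaks` (k27, ctcf, tf), `libraries` (k27_a, k27_b, ctcf_a,
#'   ctcf_b), `genes`, `expression`, and optionally `truth`.
#' @param alpha significance level for loop calling and differential tests.
#' @param min_distance cis-far distance floor in bp.
#' @param B enrichment resampling draws.
#' @param window TSS window in bp.
#' @param fold_threshold differential fold-change threshold.
#' @param seed seed for the enrichment resampling.
#' @param up_genes,down_genes differentially expressed gene sets; default
#'   to the bundle's planted truth sets when present.
#' @param out_dir optional output directory for tables and manifest.
#' @return list of class `loopforge_run` with elements `calls` (per
#'   library), `diff` (k27, ctcf), `enrichment`, `crossings`,
#'   `crossed_genes`, `contingency`, `geneset_scores`, `manifest`.
#' @export
run_pipeline <- function(bundle, alpha = 0.05, min_distance = 10000,
                         B = 500, window = 3000, fold_threshold = 1.5,
                         seed = 1L, up_genes = NULL, down_genes = NULL,
                         out_dir = NULL) {
  libs <- bundle$libraries
  need <- c("k27_a", "k27_b", "ctcf_a", "ctcf_b")
  if (!all(need %in% names(libs))) {
    stop("bundle$libraries must contain ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  up_genes <- up_genes %||% bundle$truth$de_genes$up
  down_genes <- down_genes %||% bundle$truth$de_genes$down
  if (is.null(up_genes) || is.null(down_genes)) {
    stop("up/down gene sets are required (no truth record in bundle)",
         call. = FALSE)
  }

  calls <- list(
    k27_a = call_loops(libs$k27_a, bundle$peaks$k27, alpha = alpha,
                       min_distance = min_distance),
    k27_b = call_loops(libs$k27_b, bundle$peaks$k27, alpha = alpha,
                       min_distance = min_distance),
    ctcf_a = call_loops(libs$ctcf_a, bundle$peaks$ctcf, alpha = alpha,
                        min_distance = min_distance),
    ctcf_b = call_loops(libs$ctcf_b, bundle$peaks$ctcf, alpha = alpha,
                        min_distance = min_distance)
  )

  diff <- list(
    k27 = diff_loops(libs$k27_a, libs$k27_b, alpha = alpha,
                     fold_threshold = fold_threshold),
    ctcf = diff_loops(libs$ctcf_a, libs$ctcf_b, alpha = alpha,
                      fold_threshold = fold_threshold)
  )

  ctcf_res <- diff$ctcf$results
  up_rows <- ctcf_res[ctcf_res$direction == "up", , drop = FALSE]
  universe <- unique(rbind(library_anchors(libs$ctcf_a),
                           library_anchors(libs$ctcf_b)))
  enrichment <- NULL
  if (nrow(up_rows)) {
    target <- unique(rbind(
      data.frame(chrom = up_rows$chrom, start = up_rows$start1,
                 end = up_rows$end1),
      data.frame(chrom = up_rows$chrom, start = up_rows$start2,
                 end = up_rows$end2)
    ))
    enrichment <- oe_enrichment(target, universe, bundle$peaks$tf, B = B,
                                seed = seed)
  }

  k27_res <- diff$k27$results
  k27_down <- k27_res[k27_res$direction == "down", , drop = FALSE]
  crossings <- find_crossings(k27_down, up_rows)
  crossed_genes <- crossed_loop_genes(crossings, k27_down, bundle$genes,
                                      window = window)
  contingency <- if (length(crossed_genes)) {
    crossover_contingency(crossed_genes, up_genes, down_genes)
  } else NULL

  geneset_scores <- geneset_zscore(bundle$expression, down_genes)

  manifest <- list(
    package_version = as.character(utils::packageVersion("loopforge")),
    seed = seed,
    parameters = list(alpha = alpha, min_distance = min_distance, B = B,
                      window = window, fold_threshold = fold_threshold),
    stages = list(
      n_loops = vapply(libs, function(l) nrow(l$loops), numeric(1)),
      n_significant = vapply(calls, function(x) sum(x$results$significant),
                             numeric(1)),
      n_diff_up = vapply(diff, function(d) sum(d$results$direction == "up"),
                         numeric(1)),
      n_diff_down = vapply(diff, function(d) sum(d$results$direction == "down"),
                           numeric(1)),
      n_crossings = nrow(crossings),
      n_crossed_genes = length(crossed_genes)
    )
  )

  out <- structure(
    list(calls = calls, diff = diff, enrichment = enrichment,
         crossings = crossings, crossed_genes = crossed_genes,
         contingency = contingency, geneset_scores = geneset_scores,
         manifest = manifest),
    class = "loopforge_run"
  )
  if (!is.null(out_dir)) write_run(out, out_dir)
  out
}

#' @export
print.loopforge_run <- function(x, ...) {
  s <- x$manifest$stages
  cat("loopforge pipeline run\n")
  cat(sprintf("  significant loops: %s\n",
              paste(sprintf("%s=%d", names(s$n_significant),
                            s$n_significant), collapse = ", ")))
  cat(sprintf("  differential: k27 %d up / %d down; ctcf %d up / %d down\n",
              s$n_diff_up[["k27"]], s$n_diff_down[["k27"]],
              s$n_diff_up[["ctcf"]], s$n_diff_down[["ctcf"]]))
  if (!is.null(x$enrichment)) {
    cat(sprintf("  TF enrichment at up-CTCF anchors: O/E = %.2f (p_t = %.3g)\n",
                x$enrichment$oe, x$enrichment$p_t))
  }
  cat(sprintf("  crossings: %d pairs -> %d promoter genes\n",
              s$n_crossings, s$n_crossed_genes))
  if (!is.null(x$contingency)) {
    cat(sprintf("  crossover contingency p = %.3g\n", x$contingency$p))
  }
  invisible(x)
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(run$calls)) {
    write_loop_calls(run$calls[[nm]], file.path(out_dir,
                                                paste0("calls_", nm, ".tsv")))
  }
  for (nm in names(run$diff)) {
    utils::write.table(run$diff[[nm]]$results,
                       file.path(out_dir, paste0("diff_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(run$crossings, file.path(out_dir, "crossings.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(run$crossed_genes, file.path(out_dir, "crossed_genes.txt"))
  if (!is.null(run$enrichment)) {
    e <- run$enrichment
    jsonlite::write_json(
      list(n_target = e$n_target, observed_ratio = e$observed_ratio,
           expected_ratio = e$expected_ratio, oe = e$oe, p_t = e$p_t,
           p_emp = e$p_emp, B = e$B, seed = e$seed),
      file.path(out_dir, "enrichment.json"), auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(run$contingency)) {
    ct <- run$contingency
    jsonlite::write_json(
      list(table = as.vector(ct$table), chi2 = ct$chi2, p = ct$p,
           yates = ct$yates),
      file.path(out_dir, "contingency.json"), auto_unbox = TRUE, digits = NA)
  }
  utils::write.table(run$geneset_scores,
                     file.path(out_dir, "geneset_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
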