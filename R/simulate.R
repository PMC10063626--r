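#' Synthetic HiChIP study configuration
#'
#' Builds the configuration of the seeded synthetic-data generator. The
#' generator emulates a two-mark (H3K27ac and CTCF), two-condition HiChIP
#' study: ChIP peaks double as the loop-anchor universe (one peak per
#' anchor, median-width ~2.5 kb anchors), background mated-PE counts are
#' drawn multinomially over all possible intra-chromosomal anchor pairs at
#' a uniform per-pair rate — exactly the null of the binomial loop caller —
#' and structure is planted on top: high-count significant loops,
#' condition-B fold changes on strong loops, gained CTCF loops that
#' interleave promoter-anchored H3K27ac loops ("disrupted" genes, with
#' matching expression loss), and TF peaks covering controlled fractions of
#' target and universe anchors.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param n_peaks_per_chrom ChIP peaks (= possible anchors) per chromosome
#'   and mark.
#' @param anchor_width_mean anchor width in bp (default 2500; widths are
#'   constant at this value, so the anchor-length correction is the
#'   identity on the defaults).
#' @param background_count_rate expected mated-PE count per possible anchor
#'   pair under the background (default 2).
#' @param background_mode "uniform" (default; every possible pair equally
#'   likely — exactly the loop caller's null) or "distance_decay" (per-pair
#'   rate proportional to 1/distance, normalized to the same mean; a
#'   deliberately misspecified background to probe the caller's robustness
#'   to the contact-distance decay of real Hi-C data).
#' @param frac_anchors_observed optional target fraction of anchors touched
#'   by at least one read; when given, overrides `background_count_rate`
#'   via rate = -log(1 - frac) / (anchors per chromosome - 1).
#' @param n_planted_loops planted significant loops per mark (default 20).
#' @param planted_multiplier rate multiplier of planted loops (default 10).
#' @param n_diff_loops planted differential loops per mark (default 10,
#'   split evenly up/down in condition B).
#' @param diff_multiplier fold change of planted differential loops
#'   (default 4). Differential and crossover loops sit on a baseline of
#'   `2 * planted_multiplier` times the background rate, i.e. strong loops.
#' @param n_disrupted_genes genes whose promoter-anchored H3K27ac loop is
#'   weakened in condition B and crossed by a gained CTCF loop (default 12).
#' @param n_up_genes,n_extra_down_genes additional differentially expressed
#'   genes unrelated to crossings (defaults 15 and 5; the down set is the
#'   disrupted genes plus the extras).
#' @param frac_k27_anchors fraction of CTCF anchors that also carry an
#'   H3K27ac peak (default 0.5).
#' @param frac_tf_anchors_target,frac_tf_anchors_universe fraction of
#'   target (dysregulated-loop) anchors, and of the whole CTCF anchor
#'   universe, overlapped by TF peaks (defaults 0.4 and 0.1).
#' @param n_genes number of genes (default 300).
#' @param expr_log2_effect absolute expression log2 fold change of planted
#'   DE genes (default 2).
#' @param expr_noise_sd per-sample log2 expression noise (default 0.25).
#' @param n_reps expression replicates per condition (default 3).
#' @param cis_far_total cis-far unique valid pairs per library (default 1e8).
#' @param seed master seed (default 1).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_chrom = 3, chrom_length = 3e7, n_peaks_per_chrom = 80,
                       anchor_width_mean = 2500,
                       background_count_rate = 2,
                       background_mode = c("uniform", "distance_decay"),
                       frac_anchors_observed = NULL,
                       n_planted_loops = 20, planted_multiplier = 10,
                       n_diff_loops = 10, diff_multiplier = 4,
                       n_disrupted_genes = 12, n_up_genes = 15,
                       n_extra_down_genes = 5,
                       frac_k27_anchors = 0.5,
                       frac_tf_anchors_target = 0.4,
                       frac_tf_anchors_universe = 0.1,
                       n_genes = 300, expr_log2_effect = 2,
                       expr_noise_sd = 0.25, n_reps = 3,
                       cis_far_total = 1e8, seed = 1L) {
  background_mode <- match.arg(background_mode)
  cfg <- as.list(environment())
  for (f in c("frac_k27_anchors", "frac_tf_anchors_target",
              "frac_tf_anchors_universe")) {
    stopifnot_scalar_number(cfg[[f]], f, min = 0, max = 1)
  }
  if (!is.null(frac_anchors_observed)) {
    stopifnot_scalar_number(frac_anchors_observed, "frac_anchors_observed",
                            min = 1e-6, max = 1 - 1e-6)
    cfg$background_count_rate <-
      -log(1 - frac_anchors_observed) / (n_peaks_per_chrom - 1)
  }
  if (planted_multiplier < 1 || diff_multiplier < 1) {
    stop("multipliers must be >= 1", call. = FALSE)
  }
  n_pairs <- n_chrom * choose(n_peaks_per_chrom, 2)
  if (n_planted_loops + n_diff_loops + n_disrupted_genes > n_pairs / 4) {
    stop("infeasible config: too many planted loops for the anchor universe",
         call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic HiChIP study configuration\n")
  cat(sprintf("  %d chromosome(s) x %g bp, %d anchors/chrom/mark (width %g bp)\n",
              x$n_chrom, x$chrom_length, x$n_peaks_per_chrom,
              x$anchor_width_mean))
  cat(sprintf("  background rate %.3g reads/pair; planted %d loops x%g, %d diff loops x%g, %d disrupted genes\n",
              x$background_count_rate, x$n_planted_loops, x$planted_multiplier,
              x$n_diff_loops, x$diff_multiplier, x$n_disrupted_genes))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}

# place non-overlapping anchor slots for both marks on one chromosome
place_chrom_slots <- function(config, n_shared) {
  n_ctcf <- config$n_peaks_per_chrom
  n_k27_free <- config$n_peaks_per_chrom - n_shared
  n_free <- n_ctcf + n_k27_free
  w <- config$anchor_width_mean
  spacing <- floor((config$chrom_length - 2 * w) / (n_free + 1))
  if (spacing <= w) stop("chromosome too short for requested peak count",
                         call. = FALSE)
  centers <- w + spacing * seq_len(n_free) +
    round(stats::runif(n_free, -spacing / 4, spacing / 4))
  start <- pmax(0, round(centers - w / 2))
  is_ctcf <- seq_len(n_free) %in% sample.int(n_free, n_ctcf)
  ctcf <- data.frame(start = start[is_ctcf], end = start[is_ctcf] + w)
  k27_free <- data.frame(start = start[!is_ctcf], end = start[!is_ctcf] + w)
  shared_idx <- sample.int(n_ctcf, n_shared)
  k27 <- rbind(k27_free, ctcf[shared_idx, , drop = FALSE])
  k27 <- k27[order(k27$start), , drop = FALSE]
  list(ctcf = ctcf, k27 = k27)
}

# all intra-chromosomal anchor pairs of one mark, across chromosomes
build_pair_table <- function(anchors) {
  rows <- lapply(split(anchors, anchors$chrom), function(a) {
    a <- a[order(a$start), , drop = FALSE]
    n <- nrow(a)
    if (n < 2L) return(NULL)
    ij <- t(utils::combn(n, 2L))
    data.frame(chrom = a$chrom[1L], i = ij[, 1L], j = ij[, 2L],
               start1 = a$start[ij[, 1L]], end1 = a$end[ij[, 1L]],
               start2 = a$start[ij[, 2L]], end2 = a$end[ij[, 2L]],
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$key <- sprintf("%s:%d-%d_%d-%d", tab$chrom,
                     as.integer(tab$start1), as.integer(tab$end1),
                     as.integer(tab$start2), as.integer(tab$end2))
  tab
}

# draw one library's counts: multinomial over pairs with given weights
draw_library <- function(pair_tab, weights, rate, cis_far_total, name,
                         condition) {
  n_total <- max(1L, round(rate * sum(weights)))
  counts <- as.numeric(stats::rmultinom(1L, n_total, prob = weights))
  keep <- counts > 0
  loops <- data.frame(
    id = pair_tab$key[keep], chrom = pair_tab$chrom[keep],
    start1 = pair_tab$start1[keep], end1 = pair_tab$end1[keep],
    start2 = pair_tab$start2[keep], end2 = pair_tab$end2[keep],
    count = counts[keep], stringsAsFactors = FALSE
  )
  loop_library(loops, name = name, cis_far_total = cis_far_total,
               condition = condition)
}

#' Simulate a two-mark, two-condition HiChIP study
#'
#' Generates, from one master seed, the full input bundle for the pipeline:
#' ChIP peak sets (H3K27ac, CTCF, TF), four loop libraries (two marks x two
#' conditions), gene models, a gene x sample expression matrix, and the
#' ground-truth record of every planting. Identical seeds give identical
#' bundles. See [sim_config()] for the generative design.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_bundle` with elements `peaks` (list: k27,
#'   ctcf, tf), `libraries` (list: k27_a, k27_b, ctcf_a, ctcf_b), `genes`,
#'   `expression`, `truth`, `config`.
#' @export
simulate_hichip <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- derive_seeds(config$seed, 9L)
  chroms <- sprintf("chr%d", seq_len(config$n_chrom))
  n_shared <- round(config$frac_k27_anchors * config$n_peaks_per_chrom)

  # 1. anchor slots
  slots <- with_seed(seeds[1L], lapply(chroms, function(ch) {
    place_chrom_slots(config, n_shared)
  }))
  mark_anchors <- function(mark) {
    do.call(rbind, lapply(seq_along(chroms), function(k) {
      a <- slots[[k]][[mark]]
      data.frame(chrom = chroms[k], start = a$start, end = a$end,
                 stringsAsFactors = FALSE)
    }))
  }
  k27_anchors <- mark_anchors("k27")
  ctcf_anchors <- mark_anchors("ctcf")

  k27_pairs <- build_pair_table(k27_anchors)
  ctcf_pairs <- build_pair_table(ctcf_anchors)

  # 2. plantings: ordinary significant loops, differential loops, and the
  # crossover design (disrupted K27 loops interleaved by gained CTCF loops)
  plan <- with_seed(seeds[2L], plan_plantings(config, k27_pairs, ctcf_pairs,
                                              k27_anchors, ctcf_anchors))

  base_mult <- 2 * config$planted_multiplier  # baseline of diff/crossover loops
  background_weights <- function(pairs) {
    if (config$background_mode == "uniform") return(rep(1, nrow(pairs)))
    # misspecified mode: rate ~ 1/distance, renormalized to mean 1 so the
    # per-pair expected count keeps the configured scale
    d <- (pairs$start2 + pairs$end2 - pairs$start1 - pairs$end1) / 2
    w <- 1 / pmax(d, 1)
    w / mean(w)
  }
  weight_scheme <- function(pairs, planted, diff_up, diff_down, gained) {
    w_a <- background_weights(pairs)
    w_a[planted] <- config$planted_multiplier
    w_a[c(diff_up, diff_down)] <- base_mult
    w_b <- w_a
    w_b[diff_up] <- base_mult * config$diff_multiplier
    w_b[diff_down] <- base_mult / config$diff_multiplier
    w_b[gained] <- base_mult
    list(a = w_a, b = w_b)
  }
  k27_w <- weight_scheme(k27_pairs, plan$k27_planted, plan$k27_up,
                         c(plan$k27_down, plan$k27_disrupted), integer())
  ctcf_w <- weight_scheme(ctcf_pairs, plan$ctcf_planted, plan$ctcf_up,
                          plan$ctcf_down, plan$ctcf_gained)

  rate <- config$background_count_rate
  libraries <- list(
    k27_a = with_seed(seeds[3L], draw_library(k27_pairs, k27_w$a, rate,
                                              config$cis_far_total, "k27_ctrl", "ctrl")),
    k27_b = with_seed(seeds[4L], draw_library(k27_pairs, k27_w$b, rate,
                                              config$cis_far_total, "k27_treated", "treated")),
    ctcf_a = with_seed(seeds[5L], draw_library(ctcf_pairs, ctcf_w$a, rate,
                                               config$cis_far_total, "ctcf_ctrl", "ctrl")),
    ctcf_b = with_seed(seeds[6L], draw_library(ctcf_pairs, ctcf_w$b, rate,
                                               config$cis_far_total, "ctcf_treated", "treated"))
  )

  # 3. genes and expression
  gene_info <- with_seed(seeds[7L], plan_genes(config, plan, k27_pairs,
                                               k27_anchors, chroms))
  expression <- with_seed(seeds[8L], draw_expression(config, gene_info))

  # 4. TF peaks at controlled anchor fractions
  target_anchors <- plan$target_anchors
  tf_peaks <- with_seed(seeds[9L],
                        place_tf_peaks(config, ctcf_anchors, target_anchors))

  truth <- list(
    planted_loop_ids = list(k27 = k27_pairs$key[plan$k27_planted],
                            ctcf = ctcf_pairs$key[plan$ctcf_planted]),
    diff_loops = list(
      k27 = data.frame(
        id = k27_pairs$key[c(plan$k27_up, plan$k27_down, plan$k27_disrupted)],
        direction = rep(c("up", "down"),
                        c(length(plan$k27_up),
                          length(plan$k27_down) + length(plan$k27_disrupted))),
        stringsAsFactors = FALSE),
      ctcf = data.frame(
        id = ctcf_pairs$key[c(plan$ctcf_up, plan$ctcf_gained, plan$ctcf_down)],
        direction = rep(c("up", "down"),
                        c(length(plan$ctcf_up) + length(plan$ctcf_gained),
                          length(plan$ctcf_down))),
        stringsAsFactors = FALSE)
    ),
    disrupted_k27_loop_ids = k27_pairs$key[plan$k27_disrupted],
    gained_ctcf_loop_ids = ctcf_pairs$key[plan$ctcf_gained],
    enriched_anchors = target_anchors,
    disrupted_genes = gene_info$disrupted,
    de_genes = list(up = gene_info$up, down = gene_info$down),
    expression_effects = gene_info$effects
  )

  structure(
    list(peaks = list(k27 = k27_anchors, ctcf = ctcf_anchors, tf = tf_peaks),
         libraries = libraries, genes = gene_info$genes,
         expression = expression, truth = truth, config = config),
    class = "sim_bundle"
  )
}

# choose planted / differential / crossover pair rows (expects live RNG)
plan_plantings <- function(config, k27_pairs, ctcf_pairs, k27_anchors,
                           ctcf_anchors) {
  n_up <- floor(config$n_diff_loops / 2)
  n_down <- config$n_diff_loops - n_up

  pick <- function(n_avail, n, used) {
    free <- setdiff(seq_len(n_avail), used)
    if (n > length(free)) stop("infeasible config: not enough anchor pairs",
                               call. = FALSE)
    if (n == 0L) integer() else sample(free, n)
  }

  # crossover: disrupted K27 loops with an interleaving gained CTCF loop
  k27_disrupted <- integer()
  ctcf_gained <- integer()
  if (config$n_disrupted_genes > 0L) {
    geom <- plan_crossovers(config, k27_pairs, ctcf_pairs, ctcf_anchors)
    k27_disrupted <- geom$k27_rows
    ctcf_gained <- geom$ctcf_rows
  }

  used_k27 <- k27_disrupted
  k27_up <- pick(nrow(k27_pairs), n_up, used_k27)
  k27_down <- pick(nrow(k27_pairs), n_down, c(used_k27, k27_up))
  k27_planted <- pick(nrow(k27_pairs), config$n_planted_loops,
                      c(used_k27, k27_up, k27_down))

  used_ctcf <- ctcf_gained
  ctcf_up <- pick(nrow(ctcf_pairs), n_up, used_ctcf)
  ctcf_down <- pick(nrow(ctcf_pairs), n_down, c(used_ctcf, ctcf_up))
  ctcf_planted <- pick(nrow(ctcf_pairs), config$n_planted_loops,
                       c(used_ctcf, ctcf_up, ctcf_down))

  # enrichment target: anchors of CTCF loops dysregulated in condition B
  up_rows <- c(ctcf_gained, ctcf_up)
  target <- unique(rbind(
    data.frame(chrom = ctcf_pairs$chrom[up_rows],
               start = ctcf_pairs$start1[up_rows],
               end = ctcf_pairs$end1[up_rows], stringsAsFactors = FALSE),
    data.frame(chrom = ctcf_pairs$chrom[up_rows],
               start = ctcf_pairs$start2[up_rows],
               end = ctcf_pairs$end2[up_rows], stringsAsFactors = FALSE)
  ))
  rownames(target) <- NULL

  list(k27_planted = k27_planted, k27_up = k27_up, k27_down = k27_down,
       k27_disrupted = k27_disrupted,
       ctcf_planted = ctcf_planted, ctcf_up = ctcf_up, ctcf_down = ctcf_down,
       ctcf_gained = ctcf_gained, target_anchors = target)
}

# pick K27 loops that a new CTCF loop can interleave: one CTCF anchor
# midpoint strictly between the K27 anchor midpoints, the other outside
plan_crossovers <- function(config, k27_pairs, ctcf_pairs, ctcf_anchors) {
  n_need <- config$n_disrupted_genes
  k27_rows <- integer()
  ctcf_rows <- integer()
  used_ctcf_anchor <- character()
  candidates <- sample(nrow(k27_pairs))
  # fast row lookup for a CTCF anchor pair
  ctcf_key <- paste(ctcf_pairs$chrom, ctcf_pairs$start1, ctcf_pairs$start2)
  for (row in candidates) {
    if (length(k27_rows) >= n_need) break
    ch <- k27_pairs$chrom[row]
    mid_a <- interval_mid(k27_pairs$start1[row], k27_pairs$end1[row])
    mid_b <- interval_mid(k27_pairs$start2[row], k27_pairs$end2[row])
    ca <- ctcf_anchors[ctcf_anchors$chrom == ch, , drop = FALSE]
    mids <- interval_mid(ca$start, ca$end)
    akey <- paste(ch, ca$start)
    inside <- which(mids > mid_a & mids < mid_b & !(akey %in% used_ctcf_anchor))
    outside <- which((mids < mid_a | mids > mid_b) &
                       !(akey %in% used_ctcf_anchor))
    if (!length(inside) || !length(outside)) next
    i_in <- inside[sample.int(length(inside), 1L)]
    i_out <- outside[sample.int(length(outside), 1L)]
    s1 <- min(ca$start[i_in], ca$start[i_out])
    s2 <- max(ca$start[i_in], ca$start[i_out])
    crow <- which(ctcf_key == paste(ch, s1, s2))
    if (!length(crow) || crow[1L] %in% ctcf_rows) next
    k27_rows <- c(k27_rows, row)
    ctcf_rows <- c(ctcf_rows, crow[1L])
    used_ctcf_anchor <- c(used_ctcf_anchor, akey[c(i_in, i_out)])
  }
  if (length(k27_rows) < n_need) {
    stop("infeasible config: could not place requested crossover loops",
         call. = FALSE)
  }
  list(k27_rows = k27_rows, ctcf_rows = ctcf_rows)
}

# gene models: disrupted genes at disrupted-loop anchors, other promoter
# genes at unrelated K27 anchors, the rest uniform (expects live RNG)
plan_genes <- function(config, plan, k27_pairs, k27_anchors, chroms) {
  n <- config$n_genes
  if (n < config$n_disrupted_genes + config$n_up_genes +
      config$n_extra_down_genes) {
    stop("n_genes too small for the requested DE gene sets", call. = FALSE)
  }
  gene_id <- sprintf("G%04d", seq_len(n))
  chrom <- sample(chroms, n, replace = TRUE)
  tss <- round(stats::runif(n, 1e4, config$chrom_length - 1e4))
  strand <- sample(c("+", "-"), n, replace = TRUE)

  # disrupted genes: TSS at the left-anchor midpoint of their K27 loop
  n_dis <- length(plan$k27_disrupted)
  if (n_dis) {
    rows <- plan$k27_disrupted
    chrom[seq_len(n_dis)] <- k27_pairs$chrom[rows]
    tss[seq_len(n_dis)] <- round(interval_mid(k27_pairs$start1[rows],
                                              k27_pairs$end1[rows]))
  }
  # a fraction of the remaining genes sit at K27 anchors away from the
  # disrupted loops, emulating ordinary promoter-anchored loops
  disrupted_anchor_keys <- if (n_dis) {
    rows <- plan$k27_disrupted
    c(paste(k27_pairs$chrom[rows], k27_pairs$start1[rows]),
      paste(k27_pairs$chrom[rows], k27_pairs$start2[rows]))
  } else character()
  free_anchors <- k27_anchors[!(paste(k27_anchors$chrom, k27_anchors$start)
                                %in% disrupted_anchor_keys), , drop = FALSE]
  others <- setdiff(seq_len(n), seq_len(n_dis))
  n_prom <- min(length(others) %/% 2L, nrow(free_anchors))
  prom_idx <- others[seq_len(n_prom)]
  at <- free_anchors[sample.int(nrow(free_anchors), n_prom), , drop = FALSE]
  chrom[prom_idx] <- at$chrom
  tss[prom_idx] <- round(interval_mid(at$start, at$end))

  genes <- data.frame(gene_id = gene_id, chrom = chrom, tss = tss,
                      strand = strand, stringsAsFactors = FALSE)
  disrupted <- gene_id[seq_len(n_dis)]
  rest <- setdiff(gene_id, disrupted)
  de_pick <- sample(rest, config$n_up_genes + config$n_extra_down_genes)
  up <- de_pick[seq_len(config$n_up_genes)]
  extra_down <- setdiff(de_pick, up)
  effects <- stats::setNames(rep(0, n), gene_id)
  effects[c(disrupted, extra_down)] <- -config$expr_log2_effect
  effects[up] <- config$expr_log2_effect
  list(genes = genes, disrupted = disrupted, up = up,
       down = c(disrupted, extra_down), effects = effects)
}

# gene x sample expression matrix on a linear scale (expects live RNG)
draw_expression <- function(config, gene_info) {
  n <- nrow(gene_info$genes)
  reps <- config$n_reps
  samples <- c(sprintf("ctrl_%d", seq_len(reps)),
               sprintf("treated_%d", seq_len(reps)))
  mu <- stats::rnorm(n, mean = 8, sd = 1)
  log2expr <- sapply(seq_along(samples), function(s) {
    eff <- if (s > reps) gene_info$effects else 0
    mu + eff + stats::rnorm(n, 0, config$expr_noise_sd)
  })
  dimnames(log2expr) <- list(gene_info$genes$gene_id, samples)
  2^log2expr
}

# TF peaks covering exact fractions of the anchor universe and target set
place_tf_peaks <- function(config, universe, target) {
  u_key <- paste(universe$chrom, universe$start)
  t_key <- unique(paste(target$chrom, target$start))
  n_pos_total <- round(config$frac_tf_anchors_universe * nrow(universe))
  n_pos_target <- min(round(config$frac_tf_anchors_target * length(t_key)),
                      n_pos_total)
  pos_target <- if (n_pos_target > 0L) sample(t_key, n_pos_target) else character()
  non_target <- setdiff(u_key, t_key)
  n_pos_rest <- min(n_pos_total - n_pos_target, length(non_target))
  pos_rest <- if (n_pos_rest > 0L) sample(non_target, n_pos_rest) else character()
  pos <- universe[u_key %in% c(pos_target, pos_rest), , drop = FALSE]
  if (!nrow(pos)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), name = character(), signal = numeric()))
  }
  # a narrow TF peak inside each positive anchor
  mid <- round(interval_mid(pos$start, pos$end))
  data.frame(chrom = pos$chrom, start = mid - 150, end = mid + 150,
             name = sprintf("tf_%d", seq_len(nrow(pos))),
             signal = round(stats::runif(nrow(pos), 5, 50), 2),
             stringsAsFactors = FALSE)
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat("Synthetic HiChIP bundle\n")
  for (nm in names(x$libraries)) {
    cat(sprintf("  %s: %d loops\n", nm, nrow(x$libraries[[nm]]$loops)))
  }
  cat(sprintf("  genes: %d; expression samples: %d; TF peaks: %d\n",
              nrow(x$genes), ncol(x$expression), nrow(x$peaks$tf)))
  cat(sprintf("  truth: %d+%d planted, %d disrupted genes\n",
              length(x$truth$planted_loop_ids$k27),
              length(x$truth$planted_loop_ids$ctcf),
              length(x$truth$disrupted_genes)))
  invisible(x)
}

#' Write a simulated bundle to disk
#'
#' Emits the exact plain-text formats the pipeline consumes: BED peak
#' sets, BEDPE loop files, a library metadata table, gene models,
#' the expression matrix, and the truth record as JSON.
#'
#' @param bundle a `sim_bundle`.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_sim_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_bed(bundle$peaks$k27, file.path(dir, "k27_peaks.bed"))
  write_bed(bundle$peaks$ctcf, file.path(dir, "ctcf_peaks.bed"))
  write_bed(bundle$peaks$tf, file.path(dir, "tf_peaks.bed"))
  meta <- do.call(rbind, lapply(names(bundle$libraries), function(nm) {
    lib <- bundle$libraries[[nm]]
    write_bedpe(lib, file.path(dir, paste0(nm, ".bedpe")))
    data.frame(name = lib$name, condition = lib$condition,
               cis_far_total = lib$cis_far_total)
  }))
  utils::write.table(meta, file.path(dir, "libraries.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$genes, file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expr <- data.frame(gene_id = rownames(bundle$expression),
                     bundle$expression, check.names = FALSE)
  utils::write.table(expr, file.path(dir, "expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(bundle$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

#' Confusion-matrix rates against a planted truth set
#'
#' @param called character vector of called ids.
#' @param truth character vector of planted (true-positive) ids.
#' @param universe character vector of all testable ids; `called` and
#'   `truth` must be subsets of it.
#' @return list with `sensitivity`, `specificity`, `fdr`, `tp`, `fp`, `fn`,
#'   `tn`.
#' @export
truth_eval <- function(called, truth, universe) {
  called <- unique(called); truth <- unique(truth)
  bad <- setdiff(c(called, truth), universe)
  if (length(bad)) {
    stop(sprintf("%d id(s) not in the universe (e.g. %s)", length(bad),
                 bad[1L]), call. = FALSE)
  }
  tp <- length(intersect(called, truth))
  fp <- length(setdiff(called, truth))
  fn <- length(setdiff(truth, called))
  tn <- length(universe) - tp - fp - fn
  list(
    sensitivity = if (length(truth)) tp / length(truth) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    fdr = if (length(called)) fp / length(called) else 0,
    tp = tp, fp = fp, fn = fn, tn = tn
  )
}
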