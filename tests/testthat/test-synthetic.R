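test_that("identical seeds give byte-identical bundles", {
  cfg <- small_planted_config(31)
  b1 <- simulate_hichip(cfg)
  b2 <- simulate_hichip(cfg)
  expect_identical(b1$libraries, b2$libraries)
  expect_identical(b1$truth, b2$truth)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_sim_bundle(b1, d1)
  write_sim_bundle(b2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  b3 <- simulate_hichip(small_planted_config(32))
  expect_false(identical(b1$libraries$k27_a$loops, b3$libraries$k27_a$loops))
})

test_that("null configs carry empty truth sets and conserve reads", {
  cfg <- small_null_config(12)
  sim <- simulate_hichip(cfg)
  expect_length(sim$truth$planted_loop_ids$k27, 0)
  expect_length(sim$truth$disrupted_genes, 0)
  expect_equal(nrow(sim$truth$diff_loops$ctcf), 0L)
  # multinomial conservation: all weights are 1 under the null, so the
  # drawn total is exactly rate * number of possible pairs
  n_pairs <- cfg$n_chrom * choose(cfg$n_peaks_per_chrom, 2)
  expect_equal(sum(sim$libraries$k27_a$loops$count),
               round(cfg$background_count_rate * n_pairs))
  expect_equal(sum(sim$libraries$ctcf_b$loops$count),
               round(cfg$background_count_rate * n_pairs))
})

test_that("planted loops are present with counts above the background", {
  sim <- simulate_hichip(small_planted_config(44))
  lib <- sim$libraries$k27_a
  planted <- sim$truth$planted_loop_ids$k27
  expect_true(all(planted %in% lib$loops$id))
  med <- median(lib$loops$count)
  planted_counts <- lib$loops$count[lib$loops$id %in% planted]
  expect_true(all(planted_counts >= med))
  # gained CTCF loops appear strong in condition B
  gained <- sim$truth$gained_ctcf_loop_ids
  expect_true(all(gained %in% sim$libraries$ctcf_b$loops$id))
})

test_that("the crossover plantings have interleaving geometry", {
  sim <- simulate_hichip(small_planted_config(3))
  k27 <- sim$libraries$k27_a$loops
  ctcf <- sim$libraries$ctcf_b$loops
  k_dis <- k27[k27$id %in% sim$truth$disrupted_k27_loop_ids, ]
  c_gain <- ctcf[ctcf$id %in% sim$truth$gained_ctcf_loop_ids, ]
  hits <- find_crossings(k_dis, c_gain)
  # every disrupted K27 loop is crossed by at least one gained CTCF loop
  expect_setequal(unique(hits$k27_loop_id), k_dis$id)
  # disrupted genes sit at the anchors of their disrupted loop
  g <- crossed_loop_genes(hits, k_dis, sim$genes)
  expect_true(all(sim$truth$disrupted_genes %in% g))
})

test_that("frac_anchors_observed derives the background rate", {
  cfg <- sim_config(n_chrom = 1, n_peaks_per_chrom = 40,
                    frac_anchors_observed = 0.5,
                    n_planted_loops = 0, planted_multiplier = 1,
                    n_diff_loops = 0, n_disrupted_genes = 0, seed = 2)
  expect_equal(cfg$background_count_rate, -log(0.5) / 39)
  sim <- simulate_hichip(cfg)
  anchors <- library_anchors(sim$libraries$k27_a)
  frac <- nrow(anchors) / cfg$n_peaks_per_chrom
  expect_gt(frac, 0.3)
  expect_lt(frac, 0.7)
})

test_that("distance-decay background favours short loops but conserves reads", {
  cfg <- sim_config(n_chrom = 1, n_peaks_per_chrom = 40,
                    background_mode = "distance_decay",
                    n_planted_loops = 0, planted_multiplier = 1,
                    n_diff_loops = 0, n_disrupted_genes = 0, seed = 19)
  sim <- simulate_hichip(cfg)
  loops <- sim$libraries$k27_a$loops
  expect_equal(sum(loops$count),
               round(cfg$background_count_rate * choose(40, 2)))
  # counts decay with distance: shortest quartile outweighs the longest
  d <- (loops$start2 + loops$end2 - loops$start1 - loops$end1) / 2
  q <- stats::quantile(d, c(0.25, 0.75))
  expect_gt(mean(loops$count[d <= q[1]]), mean(loops$count[d >= q[2]]))
})

test_that("infeasible configurations error early", {
  expect_error(sim_config(n_chrom = 1, n_peaks_per_chrom = 10,
                          n_planted_loops = 50), "infeasible")
  expect_error(sim_config(planted_multiplier = 0.5), "multipliers")
  expect_error(simulate_hichip(sim_config(n_chrom = 1, chrom_length = 1e5,
                                          n_peaks_per_chrom = 80)),
               "too short")
})

test_that("truth_eval computes confusion rates and checks the id space", {
  universe <- sprintf("L%d", 1:20)
  truth <- universe[1:5]
  perfect <- truth_eval(truth, truth, universe)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$fdr, 0)
  empty <- truth_eval(character(), truth, universe)
  expect_equal(empty$sensitivity, 0)
  expect_equal(empty$fdr, 0)
  extra <- truth_eval(c(truth, "L6"), truth, universe)
  expect_equal(extra$fdr, 1 / 6)
  expect_equal(extra$specificity, 14 / 15)
  expect_error(truth_eval("unknown", truth, universe), "not in the universe")
})
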