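test_that("correct_strength rescales counts to the reference span", {
  # anchors already at the reference span are unchanged
  expect_equal(correct_strength(10, 5000, 5000, 10000), 10)
  # wider anchors are scaled down: 10 * 10000 / 20000
  expect_equal(correct_strength(10, 10000, 10000, 10000), 5)
  expect_equal(correct_strength(0, 3000, 7000, 10000), 0)
  # a nonzero count never corrects to zero
  expect_equal(correct_strength(1, 50000, 50000, 1000), 1)
  # half-up rounding: 5 * 10000 / 20000 = 2.5 -> 3
  expect_equal(correct_strength(5, 10000, 10000, 10000), 3)
})

test_that("tally_chrom_stats estimates the anchor universe by peak proportion", {
  # 3 observed anchors, 4 peaks of which 3 inside observed -> round(3*4/3) = 4
  toy <- toy_instance()
  stats <- tally_chrom_stats(toy$lib, toy$peaks)
  expect_equal(stats$n_observed_anchors, 3L)
  expect_equal(stats$n_total_peaks, 4L)
  expect_equal(stats$n_peaks_in_observed, 3L)
  expect_equal(stats$n_possible_anchors, 4)
  expect_equal(stats$n_possible_loops_chrom, 6)

  # all peaks inside observed anchors -> universe equals observed
  peaks_all_in <- make_peaks(c(0, 100000, 200000))
  stats2 <- tally_chrom_stats(toy$lib, peaks_all_in)
  expect_equal(stats2$n_possible_anchors, 3)

  # direct arithmetic at larger numbers: round(100 * 1000 / 250) = 400
  expect_equal(round_half_up(100 * 1000 / 250), 400)

  # anchors without any matched peak violate the model
  far_peaks <- make_peaks(9e6)
  expect_error(tally_chrom_stats(toy$lib, far_peaks),
               "anchors lack matched ChIP peaks")
})

test_that("possible_loops sums per-chromosome pair counts", {
  stats <- data.frame(n_possible_loops_chrom = choose(c(400, 10), 2))
  mod <- possible_loops(stats)
  expect_equal(mod$n_possible_loops, 79800 + 45)
  expect_equal(mod$p_loop, 1 / 79845)
  expect_equal(possible_loops(
    data.frame(n_possible_loops_chrom = choose(2, 2)))$p_loop, 1)
  expect_equal(possible_loops(
    data.frame(n_possible_loops_chrom = choose(4, 2)))$n_possible_loops, 6)
  expect_error(possible_loops(data.frame(n_possible_loops_chrom = 0)),
               "no possible loops")
})

test_that("loop_pvalue is the upper binomial tail", {
  expect_equal(loop_pvalue(0, 50, 0.1), 1)
  expect_equal(loop_pvalue(3, 3, 0.5), 0.125)
  expect_equal(loop_pvalue(5, 100, 0.01),
               binom_upper_tail_oracle(5, 100, 0.01), tolerance = 1e-12)
  expect_equal(loop_pvalue(5, 100, 0.01), 0.00344, tolerance = 1e-5 / 0.00344)
  expect_error(loop_pvalue(5, 4, 0.1), "m <= n")
  # non-increasing in m
  p <- loop_pvalue(0:20, 20, 0.3)
  expect_true(all(diff(p) <= 0))
})

test_that("holm_adjust reproduces the step-down definition", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03, 0.005)),
               c(0.03, 0.06, 0.06, 0.02))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(rep(0.01, 3)), rep(0.03, 3))
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the worked toy instance is called exactly", {
  toy <- toy_instance()
  fit <- call_loops(toy$lib, toy$peaks)
  expect_equal(fit$params$n_possible_loops, 6)
  expect_equal(fit$params$p_loop, 1 / 6)
  expect_equal(fit$params$n_total_strength, 10)
  res <- fit$results[order(-fit$results$m), ]
  expect_equal(res$m, c(8, 1, 1))
  expect_equal(res$p_raw[1L], 1.944889e-05, tolerance = 1e-6)
  expect_equal(res$p_adj[1L], 3 * res$p_raw[1L])
  expect_equal(res$p_adj[1L], 5.834667e-05, tolerance = 1e-6)
  expect_true(res$significant[1L])
  expect_equal(res$p_raw[2:3], rep(0.8384944, 2), tolerance = 1e-6)
  expect_false(any(res$significant[2:3]))
})

test_that("distance filtering, alpha edge and zero counts behave", {
  toy <- toy_instance()
  # alpha = 1 makes every retained loop significant
  fit <- call_loops(toy$lib, toy$peaks, alpha = 1)
  expect_true(all(fit$results$significant))
  # a close pair (midpoint distance <= min_distance) is excluded
  anchors <- c(0, 5000, 200000)
  lib <- make_library(anchors, rbind(c(1, 2, 5), c(1, 3, 5)))
  fit2 <- call_loops(lib, make_peaks(anchors))
  expect_equal(nrow(fit2$results), 1L)
  expect_equal(fit2$n_filtered, 1L)
  # all-zero counts: no significant loops
  lib0 <- make_library(c(0, 1e5, 2e5), rbind(c(1, 2, 0), c(1, 3, 0)))
  fit0 <- call_loops(lib0, make_peaks(c(0, 1e5, 2e5)))
  expect_equal(sum(fit0$results$significant), 0L)
  expect_true(all(fit0$results$p_raw == 1))
})

test_that("Holm dominates raw p-values and p_adj is monotone when sorted", {
  sim <- simulate_hichip(small_planted_config(21))
  fit <- call_loops(sim$libraries$ctcf_a, sim$peaks$ctcf)
  res <- fit$results
  expect_true(all(res$p_adj >= res$p_raw - 1e-15))
  o <- order(res$p_raw)
  expect_true(all(diff(res$p_adj[o]) >= -1e-15))
  expect_true(all(res$p_adj <= 1))
})

test_that("BH and no-correction options change only what they should", {
  toy <- toy_instance()
  holm <- call_loops(toy$lib, toy$peaks)
  bh <- call_loops(toy$lib, toy$peaks, adjust = "BH")
  expect_equal(holm$results$p_raw, bh$results$p_raw)
  expect_true(all(bh$results$p_adj <= holm$results$p_adj + 1e-15))
  raw <- call_loops(toy$lib, toy$peaks, correction = "none")
  expect_equal(raw$results$m, raw$results$count)
})

test_that("summary and audit output carry the model parameters", {
  toy <- toy_instance()
  fit <- call_loops(toy$lib, toy$peaks)
  s <- summary(fit)
  expect_equal(s$n_significant, 1L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_loop_calls(fit, path)
  tab <- utils::read.delim(path)
  expect_equal(nrow(tab), 3L)
  audit <- jsonlite::read_json(paste0(path, ".audit.json"))
  expect_equal(audit$params$n_possible_loops, 6)
})
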