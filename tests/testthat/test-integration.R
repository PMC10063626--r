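test_that("trend pairs are classified by sign and 1.5-fold threshold", {
  expect_equal(classify_trend_pairs(1, 1), "consistent")
  expect_equal(classify_trend_pairs(1, -1), "opposite")
  expect_equal(classify_trend_pairs(1, 0.3), "neither")  # 0.3 < log2(1.5)
  expect_equal(classify_trend_pairs(c(-1, -2), c(-0.9, 3)),
               c("consistent", "opposite"))
  expect_equal(classify_trend_pairs(0.59, 0.59), "consistent")  # just above
  expect_error(classify_trend_pairs(c(1, 2), 1), "equal length")
})

test_that("chi2_2x2 handles the Yates correction and its clamp", {
  even <- chi2_2x2(matrix(10, 2, 2))
  expect_equal(even$chi2, 0)
  expect_equal(even$p, 1)
  y <- chi2_2x2(matrix(c(20, 10, 10, 20), 2, 2))
  expect_equal(y$chi2, 5.4)
  expect_equal(y$p, 0.0201, tolerance = 0.0005 / 0.0201)
  # agrees with the standard implementation, with and without correction
  tab <- matrix(c(18, 7, 4, 23), 2, 2)
  expect_equal(chi2_2x2(tab)$p, chisq.test(tab, correct = TRUE)$p.value)
  expect_equal(chi2_2x2(tab, yates = FALSE)$p,
               chisq.test(tab, correct = FALSE)$p.value)
  expect_error(chi2_2x2(matrix(c(0, 0, 5, 5), 2, 2)), "marginal")
  expect_error(chi2_2x2(matrix(1:6, 2, 3)), "2x2")
})

test_that("chi2_2x2 without Yates equals the closed form", {
  set.seed(42)
  for (i in 1:200) {
    tab <- matrix(sample(1:200, 4, replace = TRUE), 2, 2)
    expect_equal(chi2_2x2(tab, yates = FALSE)$chi2, chi2_closed_form(tab),
                 tolerance = 1e-9)
  }
})

toy_loop_df <- function(id, mid_a, mid_b, chrom = "chr1", w = 1000) {
  data.frame(id = id, chrom = chrom,
             start1 = mid_a - w / 2, end1 = mid_a + w / 2,
             start2 = mid_b - w / 2, end2 = mid_b + w / 2)
}

test_that("find_crossings detects interleaved geometry only", {
  k27 <- toy_loop_df("K", 1e5, 3e5)
  ctcf <- rbind(toy_loop_df("interleaved", 2e5, 5e5),
                toy_loop_df("nested", 1.2e5, 2.8e5),
                toy_loop_df("disjoint", 4e5, 6e5),
                toy_loop_df("containing", 0.5e5, 4e5))
  hits <- find_crossings(k27, ctcf)
  expect_equal(hits$ctcf_loop_id, "interleaved")
  hits_nested <- find_crossings(k27, ctcf, mode = "nested_inclusive")
  expect_setequal(hits_nested$ctcf_loop_id, c("interleaved", "nested"))
  # left-interleaved works symmetrically
  left <- toy_loop_df("left", 0.5e5, 2e5)
  expect_equal(nrow(find_crossings(k27, left)), 1L)
  # role swap: an interleaving pair crosses in both directions
  expect_equal(nrow(find_crossings(toy_loop_df("C", 2e5, 5e5), k27)), 1L)
  # different chromosome never crosses
  expect_equal(nrow(find_crossings(k27, toy_loop_df("x", 2e5, 5e5,
                                                    chrom = "chr2"))), 0L)
})

test_that("crossed_loop_genes returns the union of promoter genes", {
  k27 <- rbind(toy_loop_df("K1", 1e5, 3e5), toy_loop_df("K2", 6e5, 8e5))
  ctcf <- rbind(toy_loop_df("C1", 2e5, 5e5), toy_loop_df("C2", 7e5, 9e5))
  genes <- data.frame(gene_id = c("gA", "gB", "gFar"), chrom = "chr1",
                      tss = c(1e5, 6e5 + 2900 + 500, 5e5), strand = "+")
  hits <- find_crossings(k27, ctcf)
  expect_equal(nrow(hits), 2L)
  g <- crossed_loop_genes(hits, k27, genes)
  expect_setequal(g, c("gA", "gB"))
  # shared genes appear once
  expect_equal(anyDuplicated(g), 0L)
  expect_equal(crossed_loop_genes(hits[0, ], k27, genes), character())
})

test_that("crossover_contingency builds the down/up vs crossed table", {
  crossed <- sprintf("g%d", 1:10)
  down <- sprintf("g%d", 1:12)     # 10 crossed, 2 not
  up <- sprintf("h%d", 1:12)       # none crossed
  ct <- crossover_contingency(crossed, up, down)
  expect_equal(unname(ct$table["down", "crossed"]), 10)
  expect_equal(unname(ct$table["up", "crossed"]), 0)
  expect_lt(ct$p, 0.05)
  # identical proportions: p = 1 under the Yates clamp
  even <- crossover_contingency(c("a", "b", "x", "y"),
                                c("a", "b", "c", "d"),
                                c("x", "y", "z", "w"))
  expect_equal(even$p, 1)
  expect_error(crossover_contingency(crossed, c("g1", "h1"), down),
               "overlap")
  expect_error(crossover_contingency(character(), up, down), "marginal")
})

test_that("geneset_zscore standardizes per gene and averages per sample", {
  expr <- matrix(c(1, 2, 3), nrow = 1,
                 dimnames = list("g1", c("s1", "s2", "s3")))
  z <- geneset_zscore(expr, "g1")
  expect_equal(z$score, c(-1, 0, 1))
  # duplicated rows average to the same scores
  expr2 <- rbind(g1 = c(1, 2, 3), g2 = c(1, 2, 3))
  colnames(expr2) <- c("s1", "s2", "s3")
  expect_equal(geneset_zscore(expr2, c("g1", "g2"))$score, c(-1, 0, 1))
  # constant-only set errors; missing genes warn
  expr3 <- rbind(gc = c(2, 2, 2), gv = c(1, 2, 3))
  colnames(expr3) <- c("s1", "s2", "s3")
  expect_error(geneset_zscore(expr3, "gc"), "no scorable genes")
  expect_warning(geneset_zscore(expr3, c("gv", "absent")), "absent from")
  expect_error(geneset_zscore(expr[, 1, drop = FALSE], "g1"), "2 samples")
})

test_that("gene-set scores average to zero across samples", {
  sim <- simulate_hichip(small_planted_config(3))
  z <- geneset_zscore(sim$expression, sim$truth$de_genes$down)
  expect_equal(mean(z$score), 0, tolerance = 1e-9)
  expect_equal(nrow(z), ncol(sim$expression))
  # planted down genes score lower in treated samples
  treated <- grepl("^treated", z$sample_id)
  expect_lt(mean(z$score[treated]), mean(z$score[!treated]))
})
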