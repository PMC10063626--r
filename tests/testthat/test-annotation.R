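test_that("normalize_strength rescales by cis-far depth and preserves ranks", {
  lib <- loop_library(
    data.frame(chrom = "chr1", start1 = c(0, 20000), end1 = c(1000, 21000),
               start2 = c(50000, 90000), end2 = c(51000, 91000),
               count = c(30, 0), id = c("L1", "L2")),
    cis_far_total = 2e8)
  norm <- normalize_strength(lib)
  expect_equal(unname(norm[["L1"]]), 15)
  expect_equal(unname(norm[["L2"]]), 0)
  # scale equal to depth gives back the raw counts
  lib2 <- lib; lib2$cis_far_total <- 1e8
  expect_equal(unname(normalize_strength(lib2, scale = 1e8)),
               lib2$loops$count)
  # rank preservation on a simulated library
  sim_lib <- simulate_hichip(small_planted_config(2))$libraries$k27_a
  n <- normalize_strength(sim_lib)
  expect_equal(order(n), order(sim_lib$loops$count))
})

test_that("match_loops requires both anchors to overlap", {
  a <- loop_library(data.frame(chrom = "chr1", start1 = 1000, end1 = 3000,
                               start2 = 51000, end2 = 53000, count = 5,
                               id = "A1"), cis_far_total = 1e6)
  b_common <- loop_library(data.frame(chrom = "chr1", start1 = 1500,
                                      end1 = 2500, start2 = 50500,
                                      end2 = 51500, count = 2, id = "B1"),
                           cis_far_total = 1e6)
  b_oneanchor <- loop_library(data.frame(chrom = "chr1", start1 = 1500,
                                         end1 = 2500, start2 = 60000,
                                         end2 = 62000, count = 2, id = "B2"),
                              cis_far_total = 1e6)
  m1 <- match_loops(a, b_common)
  expect_equal(unname(m1$a[["A1"]]), "common")
  expect_equal(unname(m1$b[["B1"]]), "common")
  m2 <- match_loops(a, b_oneanchor)
  expect_equal(unname(m2$a[["A1"]]), "specific_A")
  expect_equal(unname(m2$b[["B2"]]), "specific_B")
})

test_that("match_loops common calls are symmetric", {
  sim <- simulate_hichip(small_planted_config(9))
  m_ab <- match_loops(sim$libraries$k27_a, sim$libraries$k27_b)
  m_ba <- match_loops(sim$libraries$k27_b, sim$libraries$k27_a)
  expect_setequal(names(m_ab$a)[m_ab$a == "common"],
                  names(m_ba$b)[m_ba$b == "common"])
})

test_that("k27_status classifies anchors as an unordered pair", {
  lib <- loop_library(
    data.frame(chrom = "chr1",
               start1 = c(0, 0, 0), end1 = c(1000, 1000, 1000),
               start2 = c(50000, 60000, 70000),
               end2 = c(51000, 61000, 71000),
               count = 1, id = c("both", "right", "none")),
    cis_far_total = 1e6)
  peaks <- data.frame(chrom = "chr1", start = c(500, 60500),
                      end = c(600, 60600))
  st <- k27_status(lib, peaks)
  expect_equal(unname(st[["both"]]), "-/+")   # only left anchor of "both"? no:
  # left anchor [0,1000) overlaps peak [500,600); right anchor of "both"
  # [50000,51000) has no peak -> -/+ ; "right" loop: left yes + 60500 yes -> +/+
  expect_equal(unname(st[["right"]]), "+/+")
  expect_equal(unname(st[["none"]]), "-/+")
})

test_that("gene_density counts TSSs strictly between anchor midpoints", {
  lib <- loop_library(data.frame(chrom = "chr1", start1 = 0, end1 = 1000,
                                 start2 = 200000, end2 = 201000, count = 1,
                                 id = "L"), cis_far_total = 1e6)
  # midpoints at 500 and 200500 -> span 200 kb
  genes <- data.frame(gene_id = sprintf("g%d", 1:6), chrom = "chr1",
                      tss = c(1000, 50000, 100000, 150000, 500, 200500),
                      strand = "+")
  d <- gene_density(lib, genes)
  # 4 TSS inside; the two at the midpoints are excluded (strict interior)
  expect_equal(unname(d[["L"]]), 4 / 0.2)
  expect_equal(unname(gene_density(lib, genes[0, ])[["L"]]), 0)
})

test_that("annotate_anchor_genes honours the 3 kb window", {
  anchor <- data.frame(chrom = "chr1", start = 10000, end = 12000)
  genes <- data.frame(gene_id = c("in", "near", "far", "inside"),
                      chrom = "chr1",
                      tss = c(11000, 12000 + 2900, 12000 + 3100, 10001),
                      strand = "+")
  hits <- annotate_anchor_genes(anchor, genes, window = 3000)
  expect_setequal(hits[[1L]], c("in", "near", "inside"))
  hits0 <- annotate_anchor_genes(anchor, genes, window = 0)
  expect_setequal(hits0[[1L]], c("in", "inside"))
})

test_that("promoter_loop_strength sums anchoring loops once per pair", {
  lib <- loop_library(
    data.frame(chrom = "chr1",
               start1 = c(10000, 10000, 300000), end1 = c(12000, 12000, 302000),
               start2 = c(100000, 200000, 400000),
               end2 = c(102000, 202000, 402000),
               count = c(5, 2.5, 7), id = c("L1", "L2", "L3")),
    cis_far_total = 1e8)
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                      tss = c(11000, 9e6), strand = "+")
  s <- promoter_loop_strength(genes, lib)  # scale 1e8 -> norm == count
  expect_equal(unname(s[["gA"]]), 7.5)
  expect_equal(unname(s[["gB"]]), 0)
  # a loop touching the TSS with both anchors is counted once
  lib2 <- loop_library(
    data.frame(chrom = "chr1", start1 = 10000, end1 = 12000,
               start2 = 13000, end2 = 15000, count = 4, id = "L"),
    cis_far_total = 1e8)
  s2 <- promoter_loop_strength(data.frame(gene_id = "g", chrom = "chr1",
                                          tss = 12500, strand = "+"), lib2)
  expect_equal(unname(s2[["g"]]), 4)
})

test_that("annotate_loops combines the per-loop descriptors", {
  sim <- simulate_hichip(small_planted_config(4))
  ann <- annotate_loops(sim$libraries$ctcf_a, k27_peaks = sim$peaks$k27,
                        genes = sim$genes, other = sim$libraries$ctcf_b)
  expect_true(all(c("norm_strength", "strength_class", "k27_status",
                    "gene_density", "match_class") %in% names(ann)))
  expect_equal(ann$strength_class, ifelse(ann$count > 10, "strong", "weak"))
  expect_true(all(ann$k27_status %in% c("+/+", "-/+", "-/-")))
})
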