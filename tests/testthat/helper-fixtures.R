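# Shared fixtures and independent oracles for the test suite.

# Compact loop-library builder: anchors given as start positions (constant
# width), loops as (i, j, count) index triples into the anchor list.
make_library <- function(anchor_starts, loops, width = 1000,
                         chrom = "chr1", cis_far_total = 1e6,
                         name = "toy") {
  df <- do.call(rbind, lapply(seq_len(nrow(loops)), function(r) {
    i <- loops[r, 1L]; j <- loops[r, 2L]
    data.frame(chrom = chrom,
               start1 = anchor_starts[i], end1 = anchor_starts[i] + width,
               start2 = anchor_starts[j], end2 = anchor_starts[j] + width,
               count = loops[r, 3L])
  }))
  loop_library(df, name = name, cis_far_total = cis_far_total)
}

# One-peak-per-anchor peak set for the anchors above, plus optional extra
# peak-only (potential-anchor) positions.
make_peaks <- function(anchor_starts, extra_starts = numeric(),
                       width = 1000, chrom = "chr1") {
  s <- c(anchor_starts, extra_starts)
  data.frame(chrom = chrom, start = s, end = s + width,
             name = sprintf("pk%d", seq_along(s)), signal = 1)
}

# The worked toy instance of the binomial caller: one chromosome, three
# observed anchors (one peak each) plus one peak-only region, loop
# strengths {8, 1, 1}. Universe: 4 possible anchors -> 6 possible loops,
# p = 1/6, n = 10.
toy_instance <- function() {
  anchors <- c(0, 100000, 200000)
  lib <- make_library(anchors,
                      rbind(c(1, 2, 8), c(1, 3, 1), c(2, 3, 1)))
  peaks <- make_peaks(anchors, extra_starts = 300000)
  list(lib = lib, peaks = peaks)
}

# Independent upper-tail binomial oracle: explicit log-space PMF summation,
# no survival-function shortcut.
binom_upper_tail_oracle <- function(m, n, p) {
  if (m <= 0) return(1)
  k <- m:n
  sum(exp(lchoose(n, k) + k * log(p) + (n - k) * log1p(-p)))
}

# Closed-form 2x2 chi-square without continuity correction.
chi2_closed_form <- function(tab) {
  tab <- matrix(as.numeric(tab), 2, 2)
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c_ + d
  n * (a * d - b * c_)^2 / ((a + b) * (c_ + d) * (a + c_) * (b + d))
}

# Holm step-down computed directly from its definition (stable sort).
holm_oracle <- function(p) {
  k <- length(p)
  o <- order(p)
  adj_sorted <- cummax(pmin(1, (k - seq_len(k) + 1) * p[o]))
  out <- numeric(k)
  out[o] <- adj_sorted
  out
}

# Reduced-size generator configs used by the heavier property suites; the
# planted effect sizes and rates stay at the study defaults.
small_null_config <- function(seed) {
  sim_config(n_chrom = 2, chrom_length = 2e7, n_peaks_per_chrom = 40,
             n_planted_loops = 0, planted_multiplier = 1,
             n_diff_loops = 0, n_disrupted_genes = 0,
             n_genes = 50, n_up_genes = 5, n_extra_down_genes = 5,
             seed = seed)
}

small_planted_config <- function(seed) {
  sim_config(n_chrom = 2, chrom_length = 2e7, n_peaks_per_chrom = 40,
             n_genes = 150, seed = seed)
}
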