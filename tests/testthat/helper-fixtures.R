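# Small fixtures built in code.

# toy sample {1, 1, 2, 4}: x_bar = 2 so the MLE is exactly 0.5
toy_counts <- function() {
  data.frame(value = c(1, 2, 4), count = c(2, 1, 1))
}

# fractional table with counts exactly n * p_i(theta): a perfect fit
exact_fit_table <- function(theta = 0.5, k = 12, n = 100) {
  data.frame(value = seq_len(k), count = n * geom1_pmf(theta, k))
}

# frequency table of a random geometric sample
random_table <- function(theta, n) {
  as_freq_table(rgeom1(n, theta))
}

market_column <- function(index) {
  runs <- market_runs()
  data.frame(value = runs$length, count = runs[[index]])
}
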