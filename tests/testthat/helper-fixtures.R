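# shared fixtures, all generated in code at test time

small_planted <- function(seed = 5) {
  simulate_classification(150, 10, 3, effect_size = 2, seed = seed)
}

tiny_ga_config <- function(seed = 5, n_generations = 5, ...) {
  ga_config(population_size = 8, n_generations = n_generations,
            local_search_iters = 2, patience = 5, fitness_repeats = 1,
            seed = seed, ...)
}

sine_recording <- function(freq = 10, fs = 250, duration = 8, amp = 1) {
  t <- (seq_len(round(fs * duration)) - 1) / fs
  eeg_recording(amp * sin(2 * pi * freq * t), fs = fs)
}

# brute-force two-pass ANOVA F (different arrangement than the implementation)
oracle_anova_f <- function(values, groups) {
  groups <- as.factor(groups)
  unname(stats::oneway.test(values ~ groups, var.equal = TRUE)$statistic)
}

# entropy-identity MI oracle: I = H(X) + H(Y) - H(X, Y)
oracle_mi_bits <- function(x, y) {
  h <- function(v) {
    p <- table(v) / length(v)
    -sum(p * log2(p))
  }
  h(x) + h(y) - h(paste(x, y, sep = "\r"))
}

# naive O(n^2) correlation integral
oracle_correlation_integral <- function(emb, r_grid, theiler = 0L) {
  n <- nrow(emb)
  cnt <- numeric(length(r_grid))
  tot <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (j - i <= theiler) next
      d <- sqrt(sum((emb[i, ] - emb[j, ])^2))
      tot <- tot + 1L
      cnt <- cnt + (d < r_grid)
    }
  }
  cnt / tot
}
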