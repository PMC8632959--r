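test_that("spectral entropy hits its closed-form anchor points", {
  expect_equal(spectral_entropy_bits(rep(1, 8)), 3)
  expect_equal(spectral_entropy_bits(c(5, 0, 0, 0)), 0)
  expect_equal(spectral_entropy_bits(c(2, 2)), 1)
  expect_error(spectral_entropy_bits(c(0, 0)), "positive mass")
})

test_that("power-spectrum entropy is bounded and extreme for tones vs noise", {
  tone <- sine_recording(10, fs = 250, duration = 4)$data[1, ]
  set.seed(1)
  noise <- rnorm(1000)
  h_tone <- power_spectrum_entropy(tone, 250)
  h_noise <- power_spectrum_entropy(noise, 250)
  nbins <- floor(1000 / 2)
  expect_gte(h_tone, 0)
  expect_lte(h_noise, log2(nbins))
  expect_lt(h_tone, h_noise)
  expect_error(power_spectrum_entropy(rep(1, 100), 250), "degenerate")
})

test_that("binary Shannon entropy matches direct evaluation and is symmetric", {
  expect_equal(shannon_binary_entropy(0.5), 1)
  expect_equal(shannon_binary_entropy(0), 0)
  expect_equal(shannon_binary_entropy(1), 0)
  expect_equal(shannon_binary_entropy(0.25), 0.8112781, tolerance = 1e-7)
  x <- seq(0, 1, by = 0.01)
  expect_equal(shannon_binary_entropy(x), shannon_binary_entropy(1 - x))
  expect_error(shannon_binary_entropy(1.2), "\\[0, 1\\]")
})

test_that("correlation integral matches the naive pairwise oracle", {
  set.seed(42)
  x <- rnorm(300)
  emb <- embed_delay(x, 3, 2)
  r_grid <- quantile(as.numeric(dist(emb[1:100, ])), c(0.1, 0.3, 0.6))
  fast <- correlation_integral(emb, r_grid, theiler_window = 2L)$c_r
  slow <- oracle_correlation_integral(emb, r_grid, theiler = 2L)
  expect_equal(fast, slow, tolerance = 1e-9)
})

test_that("correlation dimension recovers the dimensionality of known sets", {
  # points on a line segment
  d_line <- correlation_dimension(seq(0, 1, length.out = 1000),
                                  embedding_params(m = 2, tau = 1))
  expect_gte(d_line, 0.85)
  expect_lte(d_line, 1.15)
  # uniform square via interleaved coordinates
  set.seed(1)
  d_sq <- correlation_dimension(runif(2000), embedding_params(m = 2, tau = 1))
  expect_gte(d_sq, 1.7)
  expect_lte(d_sq, 2.2)
  expect_error(correlation_dimension(rep(1, 1000)), "degenerate")
})

test_that("K2 entropy separates periodic from stochastic dynamics", {
  tone <- sine_recording(10, fs = 250, duration = 8)$data[1, ]
  k2_tone <- kolmogorov_entropy(tone, embedding_params(m = 5))
  expect_lte(k2_tone, 0.05)
  set.seed(7)
  k2_noise <- kolmogorov_entropy(rnorm(2000), embedding_params(m = 5))
  expect_gt(k2_noise, k2_tone)
  expect_error(kolmogorov_entropy(rep(0, 1000)), "degenerate")
})

test_that("C0 complexity evaluates its spectral-residue definition", {
  # exact-bin sinusoid: dominant components fully retained
  tone <- sin(2 * pi * 8 * (0:1023) / 1024)
  expect_lte(c0_complexity(tone), 0.01)
  # Gaussian white noise: null value is 1 - 2/e ~ 0.264
  set.seed(3)
  c0_noise <- c0_complexity(rnorm(1024))
  expect_gte(c0_noise, 0.2)
  expect_lte(c0_noise, 0.35)
  expect_error(c0_complexity(rep(0, 100)), "degenerate")
  # always in [0, 1]
  for (s in 1:10) {
    set.seed(s)
    v <- c0_complexity(rnorm(256) + 0.5 * sin(2 * pi * 5 * (0:255) / 256))
    expect_gte(v, 0)
    expect_lte(v, 1)
  }
})

test_that("complexity ordering: tone < tone+noise < noise for K2 and C0", {
  t <- (0:1999) / 250
  tone <- sin(2 * pi * 10 * t)
  set.seed(11)
  noise <- rnorm(2000)
  mix <- tone + 0.5 * noise
  p <- embedding_params(m = 5, tau = 6)
  k2 <- c(kolmogorov_entropy(tone, p), kolmogorov_entropy(mix, p),
          kolmogorov_entropy(noise, p))
  c0 <- c(c0_complexity(tone), c0_complexity(mix), c0_complexity(noise))
  expect_true(all(diff(k2) > 0))
  expect_true(all(diff(c0) > 0))
})

test_that("band powers integrate the periodogram over the canonical bands", {
  tone <- sine_recording(10, fs = 250, duration = 4)$data[1, ]
  bp <- band_powers(tone, 250)
  expect_gte(bp$rel_power[bp$band == "alpha"], 0.9)
  expect_lte(sum(bp$rel_power), 1 + 1e-9)

  set.seed(5)
  wn <- band_powers(rnorm(20000), 250)
  # white noise: relative power roughly proportional to bandwidth / Nyquist
  expected <- (wn$high - wn$low) / 125
  expect_equal(wn$rel_power, expected, tolerance = 0.15)
  expect_error(band_powers(rep(0, 100), 250), "degenerate")
  expect_error(band_powers(tone, 60), "Nyquist")
})

test_that("the feature vector has exactly 12 deterministic named features", {
  sim <- simulate_eeg(n_channels = 2, duration = 2, fs = 250,
                      sine_components = list(c(10, 1)), noise_sd = 0.2,
                      seed = 8)
  fv <- extract_features(sim$recording)
  expect_equal(nrow(fv), 2L)
  feature_cols <- setdiff(names(fv), "channel")
  expect_length(feature_cols, 12L)
  expect_named(fv, c("channel", "pse", "shannon", "corr_dim", "k2", "c0",
                     "total_power", "rel_delta", "rel_theta", "rel_alpha",
                     "rel_beta", "rel_gamma", "peak_freq"))
  expect_true(all(vapply(fv[feature_cols], is.finite, logical(2))))
  expect_identical(fv, extract_features(sim$recording))
  # a 10 Hz tone puts alpha on top of the relative powers
  rels <- fv[1, c("rel_delta", "rel_theta", "rel_alpha", "rel_beta", "rel_gamma")]
  expect_equal(names(rels)[which.max(unlist(rels))], "rel_alpha")
  expect_error(extract_features(eeg_recording(matrix(1, 1, 500), 250)),
               "degenerate")
})

test_that("feature_matrix emits one row per channel-epoch with labels", {
  sim <- simulate_eeg(n_channels = 2, duration = 6, fs = 250, noise_sd = 0.3,
                      seed = 9)
  fm <- feature_matrix(sim$recording, length_s = 2, label = "1")
  expect_equal(nrow(fm), 2L * 3L)
  expect_true(all(c("channel", "epoch_idx", "label") %in% names(fm)))
  expect_setequal(unique(fm$epoch_idx), 1:3)
})
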