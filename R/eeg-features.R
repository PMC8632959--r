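#' One-sided periodogram
#'
#' Raw FFT periodogram of a mean-removed signal, returned as a tibble of
#' frequency (Hz) and power; the DC bin is dropped.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @return A tibble with columns `freq` and `power`.
#' @export
periodogram_tbl <- function(x, fs) {
  n <- length(x)
  if (n < 8) abort("signal too short for a periodogram (need >= 8 samples).")
  x <- x - mean(x)
  p <- Mod(fft(x))^2 / n
  k <- seq_len(floor(n / 2))
  tibble(freq = k * fs / n, power = p[k + 1L])
}

#' Shannon entropy of a normalized power distribution
#'
#' `H = -sum(p * log2(p))` with the `0 * log 0 = 0` convention.
#'
#' @param p Nonnegative weights; normalized to sum to one internally.
#' @return Entropy in bits, in `[0, log2(length(p))]`.
#' @examples
#' spectral_entropy_bits(rep(1, 8))   # 3 bits
#' spectral_entropy_bits(c(1, 0, 0))  # 0 bits
#' @export
spectral_entropy_bits <- function(p) {
  if (any(p < 0) || !any(p > 0)) abort("`p` must be nonnegative with positive mass.")
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Power-spectrum entropy of a signal
#'
#' The periodogram is normalized to a probability distribution over frequency
#' bins and its Shannon entropy (bits) is returned; a spectrally concentrated
#' signal scores near 0, broadband noise near `log2(n_bins)`.
#'
#' @param x Numeric signal (length >= 8, non-constant).
#' @param fs Sampling rate in Hz.
#' @return Entropy in bits.
#' @export
power_spectrum_entropy <- function(x, fs) {
  if (sd(x) == 0) abort("degenerate input: constant signal has no power spectrum.")
  spectral_entropy_bits(periodogram_tbl(x, fs)$power)
}

#' Binary Shannon entropy
#'
#' `H(x) = -x log2 x - (1 - x) log2(1 - x)` with `H(0) = H(1) = 0`. Applied to
#' an EEG epoch through the fraction of samples above the epoch median (see
#' [extract_features()]).
#'
#' @param x Fraction(s) in `[0, 1]`; vectorized.
#' @return Entropy in bits.
#' @examples
#' shannon_binary_entropy(0.5)   # 1
#' shannon_binary_entropy(0.25)  # 0.8112781
#' @export
shannon_binary_entropy <- function(x) {
  if (any(x < 0 | x > 1)) abort("`x` must lie in [0, 1].")
  term <- function(p) ifelse(p == 0, 0, -p * log2(p))
  term(x) + term(1 - x)
}

#' Delay-embedding parameters
#'
#' @param m Embedding dimension (>= 1).
#' @param tau Delay in samples (>= 1), or `NULL` to use the first
#'   zero-crossing of the autocorrelation function (fallback 1).
#' @param theiler_window Minimum temporal separation of point pairs entering
#'   the correlation integral, or `NULL` for `tau`.
#' @param r_grid Strictly increasing positive radii, or `NULL` to place 16
#'   log-spaced radii between the 5th and 50th percentile of a sample of
#'   pairwise distances (the default log-log scaling region).
#' @return A list of class `embedding_params`.
#' @export
embedding_params <- function(m = 5, tau = NULL, theiler_window = NULL,
                             r_grid = NULL) {
  m <- check_count(m, "m")
  if (!is.null(tau)) tau <- check_count(tau, "tau")
  if (!is.null(theiler_window)) theiler_window <- check_count(theiler_window, "theiler_window", min = 0L)
  if (!is.null(r_grid)) {
    if (any(r_grid <= 0) || any(diff(r_grid) <= 0)) {
      abort("`r_grid` must be positive and strictly increasing.")
    }
  }
  structure(list(m = m, tau = tau, theiler_window = theiler_window,
                 r_grid = r_grid),
            class = "embedding_params")
}

#' Delay embedding of a scalar series
#'
#' @param x Numeric signal.
#' @param m Embedding dimension.
#' @param tau Delay in samples.
#' @return A matrix with `length(x) - (m - 1) * tau` rows and `m` columns.
#' @export
embed_delay <- function(x, m, tau) {
  n <- length(x) - (m - 1L) * tau
  if (n < 1) abort("`m * tau` too large for this signal length.")
  idx <- outer(seq_len(n), (seq_len(m) - 1L) * tau, `+`)
  matrix(x[idx], nrow = n)
}

first_zero_crossing_tau <- function(x) {
  a <- as.numeric(acf(x, lag.max = min(length(x) - 1L, 200L), plot = FALSE)$acf)[-1]
  idx <- which(a <= 0)
  if (length(idx)) idx[1] else 1L
}

resolve_embedding <- function(x, params) {
  tau <- params$tau %||% first_zero_crossing_tau(x)
  theiler <- params$theiler_window %||% tau
  list(m = params$m, tau = tau, theiler = theiler, r_grid = params$r_grid)
}

#' Correlation integral of an embedded point cloud
#'
#' `C(r)` = fraction of point pairs (separated in time by more than the Theiler
#' window) whose Euclidean distance is below `r`.
#'
#' @param emb Embedded points (rows), e.g. from [embed_delay()].
#' @param r_grid Radii at which to evaluate `C(r)`.
#' @param theiler_window Minimum index separation of counted pairs.
#' @return A tibble with columns `r` and `c_r`.
#' @export
correlation_integral <- function(emb, r_grid, theiler_window = 0L) {
  n <- nrow(emb)
  d <- as.matrix(stats::dist(emb))
  ij <- which(upper.tri(d), arr.ind = TRUE)
  keep <- (ij[, 2] - ij[, 1]) > theiler_window
  dd <- d[upper.tri(d)][keep]
  if (!length(dd)) abort("no admissible point pairs (Theiler window too wide).")
  tibble(r = r_grid,
         c_r = vapply(r_grid, function(r) mean(dd < r), numeric(1)))
}

default_r_grid <- function(emb, theiler_window) {
  n <- nrow(emb)
  set <- if (n > 600) emb[seq(1, n, length.out = 600), , drop = FALSE] else emb
  dd <- as.numeric(stats::dist(set))
  dd <- dd[dd > 0]
  if (!length(dd)) abort("degenerate input: all embedded points identical.")
  qs <- quantile(dd, c(0.05, 0.50))
  exp(seq(log(qs[[1]]), log(qs[[2]]), length.out = 16))
}

#' Correlation dimension (Grassberger-Procaccia)
#'
#' Delay-embeds the signal, evaluates the correlation integral `C(r)` over the
#' scaling-region radii, and returns the least-squares slope of
#' `log C(r)` versus `log r` — the scaling exponent `C(r) ~ r^D`.
#'
#' @param x Numeric signal.
#' @param params An [embedding_params()].
#' @return The estimated dimension (a real scalar).
#' @examples
#' correlation_dimension(seq(0, 1, length.out = 1000), embedding_params(m = 2, tau = 1))
#' @export
correlation_dimension <- function(x, params = embedding_params()) {
  if (sd(x) == 0) abort("degenerate input: constant signal.")
  ep <- resolve_embedding(x, params)
  emb <- embed_delay(x, ep$m, ep$tau)
  if (nrow(emb) < 50) abort("too few embedded points (need >= 50).")
  r_grid <- ep$r_grid %||% default_r_grid(emb, ep$theiler)
  ci <- correlation_integral(emb, r_grid, ep$theiler)
  ci <- ci[ci$c_r > 0, ]
  if (nrow(ci) < 2) abort("correlation integral vanished over the scaling region.")
  unname(stats::coef(stats::lm(log(c_r) ~ log(r), data = ci))[2])
}

#' Kolmogorov (K2) entropy
#'
#' The correlation-entropy estimator: with correlation integrals `C_m(r)` and
#' `C_{m+1}(r)` at consecutive embedding dimensions,
#' `K2 = mean over r of log(C_m(r) / C_{m+1}(r)) / tau` (nats per sample) over
#' the scaling-region radii. Near zero for deterministic periodic signals;
#' larger for more chaotic/stochastic ones.
#'
#' @inheritParams correlation_dimension
#' @return K2 estimate in nats per sample.
#' @export
kolmogorov_entropy <- function(x, params = embedding_params()) {
  if (sd(x) == 0) abort("degenerate input: constant signal.")
  ep <- resolve_embedding(x, params)
  emb_m <- embed_delay(x, ep$m, ep$tau)
  emb_m1 <- embed_delay(x, ep$m + 1L, ep$tau)
  n1 <- nrow(emb_m1)
  if (n1 < 50) abort("too few embedded points (need >= 50).")
  emb_m <- emb_m[seq_len(n1), , drop = FALSE]  # common point count
  r_grid <- ep$r_grid %||% default_r_grid(emb_m, ep$theiler)
  c_m <- correlation_integral(emb_m, r_grid, ep$theiler)$c_r
  c_m1 <- correlation_integral(emb_m1, r_grid, ep$theiler)$c_r
  ok <- c_m > 0 & c_m1 > 0
  if (!any(ok)) abort("degenerate input: correlation integrals vanish at m + 1.")
  mean(log(c_m[ok] / c_m1[ok])) / ep$tau
}

#' C0 complexity
#'
#' Fraction of signal energy carried by "weak" Fourier components: the DFT
#' coefficients whose squared magnitude exceeds the mean squared magnitude are
#' retained, the rest are zeroed, the inverse transform gives the regular part
#' `Y(n)`, and `C0 = sum |X - Y|^2 / sum |X|^2`. Always in `[0, 1]`; near 0 for
#' a single-tone signal, approaching `1 - 2/e` (about 0.26) for Gaussian white
#' noise.
#'
#' @param x Numeric signal (not all zero).
#' @return C0 complexity in `[0, 1]`.
#' @export
c0_complexity <- function(x) {
  if (all(x == 0)) abort("degenerate input: all-zero signal.")
  n <- length(x)
  xt <- fft(x)
  pw <- Mod(xt)^2
  keep <- pw > mean(pw)
  y <- Re(fft(ifelse(keep, xt, 0 + 0i), inverse = TRUE)) / n
  sum((x - y)^2) / sum(x^2)
}

default_bands <- function() {
  tibble(band = c("delta", "theta", "alpha", "beta", "gamma"),
         low = c(0.5, 4, 8, 13, 30), high = c(4, 8, 13, 30, 45))
}

#' Absolute and relative band power
#'
#' Integrates the periodogram over the classical EEG bands (delta 0.5-4,
#' theta 4-8, alpha 8-13, beta 13-30, gamma 30-45 Hz by default). Relative
#' powers are fractions of total (non-DC) periodogram power and therefore sum
#' to at most 1.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz; must cover the requested bands.
#' @param bands A tibble with columns `band`, `low`, `high`.
#' @return A tibble with columns `band`, `low`, `high`, `abs_power`,
#'   `rel_power`.
#' @export
band_powers <- function(x, fs, bands = default_bands()) {
  if (all(x == 0) || sd(x) == 0) abort("degenerate input: constant signal.")
  if (any(bands$high > fs / 2)) abort("band edges must lie below the Nyquist frequency.")
  pg <- periodogram_tbl(x, fs)
  total <- sum(pg$power)
  dplyr::mutate(
    bands,
    abs_power = purrr::map2_dbl(.data$low, .data$high, function(lo, hi) {
      sum(pg$power[pg$freq > lo & pg$freq <= hi])
    }),
    rel_power = .data$abs_power / total
  )
}

#' The 12-component feature vector of one channel-epoch
#'
#' Computes, per channel of an epoch: power-spectrum entropy; Shannon entropy
#' of the signal binarized at the epoch median; correlation dimension; K2
#' entropy; C0 complexity; total spectral power; relative delta, theta, alpha,
#' beta and gamma power; and the spectral peak frequency — 12 named features.
#'
#' @param epoch An [eeg_recording()] epoch (all channels are processed) or a
#'   numeric vector with `fs` supplied.
#' @param fs Sampling rate, required when `epoch` is a numeric vector.
#' @param params An [embedding_params()] shared by the correlation-integral
#'   features.
#' @return A tibble with one row per channel: `channel` plus the 12 feature
#'   columns `pse`, `shannon`, `corr_dim`, `k2`, `c0`, `total_power`,
#'   `rel_delta`, `rel_theta`, `rel_alpha`, `rel_beta`, `rel_gamma`,
#'   `peak_freq`.
#' @export
extract_features <- function(epoch, fs = NULL, params = embedding_params()) {
  if (is.numeric(epoch) && is.null(dim(epoch))) {
    if (is.null(fs)) abort("`fs` is required for a bare numeric signal.")
    epoch <- eeg_recording(epoch, fs)
  }
  stopifnot(inherits(epoch, "eeg_recording"))
  fs <- epoch$fs
  purrr::map_dfr(seq_len(nrow(epoch$data)), function(ch) {
    x <- epoch$data[ch, ]
    if (sd(x) == 0) {
      abort(sprintf("degenerate input on channel %s: constant signal.",
                    epoch$channel_labels[ch]))
    }
    bp <- band_powers(x, fs)
    pg <- periodogram_tbl(x, fs)
    tibble(
      channel = epoch$channel_labels[ch],
      pse = power_spectrum_entropy(x, fs),
      shannon = shannon_binary_entropy(mean(x > median(x))),
      corr_dim = correlation_dimension(x, params),
      k2 = kolmogorov_entropy(x, params),
      c0 = c0_complexity(x),
      total_power = sum(pg$power),
      rel_delta = bp$rel_power[bp$band == "delta"],
      rel_theta = bp$rel_power[bp$band == "theta"],
      rel_alpha = bp$rel_power[bp$band == "alpha"],
      rel_beta = bp$rel_power[bp$band == "beta"],
      rel_gamma = bp$rel_power[bp$band == "gamma"],
      peak_freq = pg$freq[which.max(pg$power)]
    )
  })
}

#' Feature matrix over all epochs of a recording
#'
#' Epochs the recording and applies [extract_features()] to every epoch,
#' returning one row per channel-epoch.
#'
#' @param rec An [eeg_recording()].
#' @param length_s,overlap_s Epoching parameters, see [epoch_recording()].
#' @param params An [embedding_params()].
#' @param label Optional label attached to every row (e.g. the subject's
#'   class).
#' @return A tibble with `channel`, `epoch_idx`, the 12 feature columns, and
#'   optionally `label`.
#' @export
feature_matrix <- function(rec, length_s = 2, overlap_s = 0,
                           params = embedding_params(), label = NULL) {
  eps <- epoch_recording(rec, length_s, overlap_s)
  out <- purrr::imap_dfr(eps, function(e, i) {
    dplyr::mutate(extract_features(e, params = params), epoch_idx = i,
                  .after = "channel")
  })
  if (!is.null(label)) out$label <- label
  out
}
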