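#' Simulate a labeled classification dataset with planted informative features
#'
#' Generates a samples x features Gaussian matrix with a binary `label` column.
#' Exactly `n_informative` features carry a class-conditional mean shift of
#' `effect_size` standard deviations (applied to class 1 only); the remaining
#' features are class-independent noise. The indices of the planted features are
#' attached as the `informative` attribute — ground truth never appears in the
#' data matrix itself.
#'
#' @param n_samples Number of rows.
#' @param n_features Number of feature columns (named `f01`, `f02`, ...).
#' @param n_informative Number of planted informative features
#'   (`<= n_features`).
#' @param effect_size Standardized mean shift (>= 0) of informative features
#'   between the two classes.
#' @param class_balance Fraction of samples in class 1, in (0, 1).
#' @param seed Integer seed; identical seeds give identical datasets.
#' @return A tibble of class `fawfs_dataset` with feature columns and a factor
#'   `label` (levels "0", "1"); attribute `informative` holds the planted
#'   column indices.
#' @examples
#' d <- simulate_classification(100, 10, n_informative = 3, effect_size = 2, seed = 1)
#' attr(d, "informative")
#' @export
simulate_classification <- function(n_samples, n_features, n_informative,
                                    effect_size = 1, class_balance = 0.5,
                                    seed = 1L) {
  n_samples <- check_count(n_samples, "n_samples")
  n_features <- check_count(n_features, "n_features")
  n_informative <- check_count(n_informative, "n_informative", min = 0L)
  if (n_informative > n_features) {
    abort("`n_informative` must not exceed `n_features`.")
  }
  effect_size <- check_number(effect_size, "effect_size", min = 0)
  class_balance <- check_number(class_balance, "class_balance",
                                min = 0, max = 1, open_min = TRUE, open_max = TRUE)

  withr::with_seed(seed, {
    n1 <- round(n_samples * class_balance)
    y <- c(rep(1L, n1), rep(0L, n_samples - n1))
    y <- sample(y)
    x <- matrix(rnorm(n_samples * n_features), n_samples, n_features)
    informative <- if (n_informative > 0) sort(sample.int(n_features, n_informative)) else integer(0)
    if (length(informative)) {
      x[y == 1L, informative] <- x[y == 1L, informative] + effect_size
    }
    colnames(x) <- sprintf("f%02d", seq_len(n_features))
    out <- as_tibble(as.data.frame(x))
    out$label <- factor(y, levels = c(0L, 1L))
    attr(out, "informative") <- informative
    class(out) <- c("fawfs_dataset", class(out))
    out
  })
}

#' Simulate a multichannel EEG recording with planted ocular artifacts
#'
#' Each channel is a sum of sinusoids plus Gaussian noise; blinks are planted as
#' raised-cosine pulses of 300 ms at 5x the clean-signal standard deviation,
#' placed uniformly at random without overlap (the same blink train on every
#' channel, as frontal EOG contamination is strongly correlated across
#' Fp1/Fp2/Fpz). Returns the contaminated recording, the blink-free reference,
#' and the blink metadata.
#'
#' @param n_channels Number of channels.
#' @param duration Recording length in seconds (> 0).
#' @param fs Sampling rate in Hz (default 1000).
#' @param sine_components List of `c(frequency_hz, amplitude)` pairs.
#' @param n_blinks Number of planted blink artifacts (>= 0).
#' @param noise_sd Standard deviation of additive Gaussian noise (>= 0).
#' @param seed Integer seed.
#' @return A list of class `eeg_sim`: `recording` (contaminated
#'   [eeg_recording()]), `clean` (blink-free reference), and `blinks`
#'   (tibble with `onset_s`, `center_s`, `amplitude`).
#' @examples
#' sim <- simulate_eeg(duration = 2, n_blinks = 3, seed = 7)
#' nrow(sim$blinks)
#' @export
simulate_eeg <- function(n_channels = 3, duration = 10, fs = 1000,
                         sine_components = list(c(10, 1)),
                         n_blinks = 0, noise_sd = 0.5, seed = 1L) {
  n_channels <- check_count(n_channels, "n_channels")
  duration <- check_number(duration, "duration", min = 0, open_min = TRUE)
  fs <- check_number(fs, "fs", min = 0, open_min = TRUE)
  n_blinks <- check_count(n_blinks, "n_blinks", min = 0L)
  noise_sd <- check_number(noise_sd, "noise_sd", min = 0)

  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  labels <- c("Fp1", "Fp2", "Fpz", paste0("ch", seq_len(max(0, n_channels - 3)) + 3L))
  labels <- labels[seq_len(n_channels)]

  withr::with_seed(seed, {
    base <- rowSums(vapply(
      sine_components,
      function(co) co[2] * sin(2 * pi * co[1] * t),
      numeric(n)
    ))
    clean <- matrix(0, n_channels, n)
    for (ch in seq_len(n_channels)) {
      clean[ch, ] <- base + rnorm(n, sd = noise_sd)
    }
    sig_sd <- max(sd(clean[1, ]), 1e-12)

    blink_len <- round(0.3 * fs)
    blinks <- tibble(onset_s = numeric(0), center_s = numeric(0),
                     amplitude = numeric(0))
    artifact <- numeric(n)
    if (n_blinks > 0) {
      if (n < n_blinks * blink_len) {
        abort("recording too short to place the requested blinks without overlap.")
      }
      # rejection-sample non-overlapping onsets
      onsets <- integer(0)
      while (length(onsets) < n_blinks) {
        cand <- sample.int(n - blink_len + 1L, 1L)
        if (!any(abs(cand - onsets) < blink_len)) onsets <- c(onsets, cand)
      }
      onsets <- sort(onsets)
      amp <- 5 * sig_sd
      pulse <- amp * (1 - cos(2 * pi * seq_len(blink_len) / (blink_len + 1))) / 2
      for (o in onsets) artifact[o:(o + blink_len - 1L)] <- artifact[o:(o + blink_len - 1L)] + pulse
      blinks <- tibble(
        onset_s = (onsets - 1) / fs,
        center_s = (onsets - 1 + blink_len / 2) / fs,
        amplitude = amp
      )
    }
    contaminated <- sweep(clean, 2, artifact, "+")
    structure(
      list(
        recording = eeg_recording(contaminated, fs, labels),
        clean = eeg_recording(clean, fs, labels),
        blinks = blinks
      ),
      class = "eeg_sim"
    )
  })
}

#' Simulate a two-group pre/post clinical cohort
#'
#' Draws per-patient rating-scale scores at two timepoints for a control and an
#' intervention group of equal size. Post scores drop by `control_reduction`
#' points in both groups and by an additional `intervention_effect` points in
#' the intervention group, so the expected post-score difference
#' (control - intervention) equals `intervention_effect`. Scores are clamped to
#' each instrument's admissible range (SAS/SDS index 25-100, HAMD 0-68,
#' GQOLI-74 subscales 0-100).
#'
#' @param n_per_group Patients per group (>= 2).
#' @param instruments Character vector of instruments to score.
#' @param pre_mean,pre_sd Pre-intervention score distribution parameters. A
#'   scalar `pre_mean` applies to all instruments; `NULL` uses per-instrument
#'   defaults (SAS/SDS 62, HAMD 25, GQOLI-74 subscales 55 — moderate symptom
#'   load on each instrument's own scale).
#' @param control_reduction Mean pre-to-post drop in both groups, scale points.
#' @param intervention_effect Additional mean post-score reduction in the
#'   intervention group relative to control, scale points.
#' @param post_sd Residual SD of the post score around its group mean.
#' @param seed Integer seed.
#' @return A tibble with columns `group`, `patient_id`, `instrument`,
#'   `timepoint`, `score`.
#' @examples
#' coh <- simulate_cohort(n_per_group = 27, seed = 1)
#' dplyr::count(coh, group, timepoint)
#' @export
simulate_cohort <- function(n_per_group = 27,
                            instruments = c("SAS", "SDS", "HAMD"),
                            pre_mean = NULL, pre_sd = 6,
                            control_reduction = 8, intervention_effect = 6,
                            post_sd = 5, seed = 1L) {
  n_per_group <- check_count(n_per_group, "n_per_group", min = 2L)
  pre_sd <- check_number(pre_sd, "pre_sd", min = 0)
  post_sd <- check_number(post_sd, "post_sd", min = 0)

  ranges <- list(
    SAS = c(25, 100), SDS = c(25, 100), HAMD = c(0, 68),
    GQOLI74_physical = c(0, 100), GQOLI74_psychological = c(0, 100),
    GQOLI74_social = c(0, 100), GQOLI74_substance = c(0, 100)
  )
  bad <- setdiff(instruments, names(ranges))
  if (length(bad)) abort(paste0("unknown instrument(s): ", paste(bad, collapse = ", ")))
  default_means <- c(
    SAS = 62, SDS = 62, HAMD = 25,
    GQOLI74_physical = 55, GQOLI74_psychological = 55,
    GQOLI74_social = 55, GQOLI74_substance = 55
  )
  means <- if (is.null(pre_mean)) default_means[instruments] else
    setNames(rep_len(pre_mean, length(instruments)), instruments)

  withr::with_seed(seed, {
    grid <- tidyr::expand_grid(
      group = c("control", "intervention"),
      patient_no = seq_len(n_per_group),
      instrument = instruments
    )
    grid$patient_id <- sprintf("%s_%02d", substr(grid$group, 1, 3), grid$patient_no)
    pre <- means[grid$instrument] + rnorm(nrow(grid), sd = pre_sd)
    drop <- control_reduction +
      ifelse(grid$group == "intervention", intervention_effect, 0)
    post <- pre - drop + rnorm(nrow(grid), sd = post_sd)
    clamp <- function(x, instrument) {
      lo <- vapply(ranges[instrument], `[`, numeric(1), 1L)
      hi <- vapply(ranges[instrument], `[`, numeric(1), 2L)
      pmin(pmax(x, lo), hi)
    }
    out <- dplyr::bind_rows(
      dplyr::mutate(grid, timepoint = "pre", score = clamp(pre, .data$instrument)),
      dplyr::mutate(grid, timepoint = "post", score = clamp(post, .data$instrument))
    )
    dplyr::arrange(
      dplyr::select(out, "group", "patient_id", "instrument", "timepoint", "score"),
      .data$group, .data$patient_id, .data$instrument,
      dplyr::desc(.data$timepoint)
    )
  })
}

#' Read / write a labeled dataset as CSV
#'
#' CSV with a header row and the class column named `label`.
#'
#' @param data A data frame with a `label` column.
#' @param path File path.
#' @param label Name of the label column on read.
#' @return `write_dataset_csv()` returns `path` invisibly; `read_dataset_csv()`
#'   a tibble with `label` as a factor.
#' @export
write_dataset_csv <- function(data, path) {
  if (!"label" %in% names(data)) abort("`data` must contain a `label` column.")
  readr::write_csv(as_tibble(data), path)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path, label = "label") {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!label %in% names(df)) abort(sprintf("no `%s` column in %s.", label, path))
  df[[label]] <- factor(df[[label]])
  if (label != "label") names(df)[names(df) == label] <- "label"
  df
}
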