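#' EEG recording container
#'
#' A minimal multichannel time-series container: a channels x samples numeric
#' matrix in microvolts, a sampling rate in Hz, and one label per channel
#' (frontal montages such as Fp1/Fp2/Fpz are the typical use).
#'
#' @param data Numeric matrix, channels x samples, or a numeric vector for a
#'   single channel.
#' @param fs Sampling rate in Hz (> 0).
#' @param channel_labels Character vector, one label per channel. Defaults to
#'   `ch1`, `ch2`, ...
#' @return An object of class `eeg_recording`.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(2000), nrow = 2), fs = 250)
#' rec
#' @export
eeg_recording <- function(data, fs, channel_labels = NULL) {
  if (is.vector(data) && is.numeric(data)) data <- matrix(data, nrow = 1L)
  if (!is.matrix(data) || !is.numeric(data)) {
    abort("`data` must be a numeric channels x samples matrix.")
  }
  if (!all(is.finite(data))) abort("`data` must be finite everywhere.")
  fs <- check_number(fs, "fs", min = 0, open_min = TRUE)
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(nrow(data)))
  if (length(channel_labels) != nrow(data)) {
    abort("`channel_labels` must have one entry per channel.")
  }
  structure(
    list(data = unname(data), fs = fs, channel_labels = as.character(channel_labels)),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channel(s) x %d samples @ %g Hz (%.3f s)\n",
    nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs
  ))
  cat("channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

n_samples <- function(rec) ncol(rec$data)

rec_duration <- function(rec) ncol(rec$data) / rec$fs

#' @describeIn eeg_recording Convert to a wide tibble with a `time_s` column
#'   and one column per channel.
#' @param x An `eeg_recording`.
#' @param ... Unused.
#' @export
as_tibble.eeg_recording <- function(x, ...) {
  out <- as_tibble(setNames(
    as.data.frame(t(x$data)), x$channel_labels
  ))
  dplyr::bind_cols(tibble(time_s = (seq_len(ncol(x$data)) - 1) / x$fs), out)
}

#' Read / write an EEG recording as wide CSV
#'
#' The wide-CSV layout is `time_s` plus one column per channel; the sampling
#' rate is recovered from the median spacing of `time_s` on read.
#'
#' @param rec An [eeg_recording()].
#' @param path File path.
#' @return `write_eeg_csv()` returns `path` invisibly; `read_eeg_csv()` returns
#'   an [eeg_recording()].
#' @export
write_eeg_csv <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  readr::write_csv(as_tibble(rec), path)
  invisible(path)
}

#' @rdname write_eeg_csv
#' @export
read_eeg_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!"time_s" %in% names(df)) abort("wide EEG CSV must contain a `time_s` column.")
  dt <- median(diff(df$time_s))
  chans <- setdiff(names(df), "time_s")
  eeg_recording(t(as.matrix(df[chans])), fs = 1 / dt, channel_labels = chans)
}

#' Cut a recording into fixed-length epochs
#'
#' Epochs tile the recording with stride `length_s - overlap_s`; a trailing
#' window that would run past the end is discarded.
#'
#' @param rec An [eeg_recording()].
#' @param length_s Epoch length in seconds.
#' @param overlap_s Overlap between consecutive epochs in seconds
#'   (`0 <= overlap_s < length_s`).
#' @return A list of `eeg_recording` epochs.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(2500), nrow = 1), fs = 250)
#' length(epoch_recording(rec, 2))        # 5 epochs
#' length(epoch_recording(rec, 2, 1))     # 9 epochs
#' @export
epoch_recording <- function(rec, length_s, overlap_s = 0) {
  stopifnot(inherits(rec, "eeg_recording"))
  length_s <- check_number(length_s, "length_s", min = 0, open_min = TRUE)
  overlap_s <- check_number(overlap_s, "overlap_s", min = 0)
  if (overlap_s >= length_s) abort("`overlap_s` must be smaller than `length_s`.")
  if (length_s > rec_duration(rec) + 1e-12) {
    abort("epoch length exceeds the recording duration.")
  }
  len <- round(length_s * rec$fs)
  stride <- round((length_s - overlap_s) * rec$fs)
  starts <- seq(1L, n_samples(rec) - len + 1L, by = stride)
  lapply(starts, function(s) {
    eeg_recording(rec$data[, s:(s + len - 1L), drop = FALSE], rec$fs,
                  rec$channel_labels)
  })
}

#' @describeIn eeg_recording Channel traces over time, faceted by channel.
#' @param object An `eeg_recording`.
#' @export
autoplot.eeg_recording <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object), -"time_s",
                            names_to = "channel", values_to = "amplitude")
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel)) +
    ggplot2::labs(x = "time (s)", y = "amplitude (µV)")
}
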