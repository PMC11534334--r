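#' Epoched EEG data
#'
#' Container for event-locked EEG segments: a 3-D array
#' `epochs x channels x samples`, the epoch window in seconds relative to
#' event onset (half-open `[t_min, t_max)`), the sampling rate, and the
#' per-epoch event metadata.
#'
#' @param data numeric array epochs x channels x samples.
#' @param window numeric length-2, `(t_min, t_max)` seconds relative to onset.
#' @param fs sampling rate in Hz.
#' @param channels channel labels.
#' @param events data.frame of per-epoch event metadata (one row per epoch).
#' @return object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, window, fs, channels, events = NULL) {
  stopifnot(length(dim(data)) == 3)
  n_samp <- round((window[2] - window[1]) * fs)
  if (dim(data)[3] != n_samp) {
    stopf("epoch length %d != round((t_max - t_min) * fs) = %d",
          dim(data)[3], n_samp)
  }
  structure(
    list(data = data, window = as.numeric(window), fs = fs,
         channels = as.character(channels), events = events),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("<eeg_epochs> %d epochs x %d channels x %d samples @ %g Hz, window [%g, %g) s\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$fs,
              x$window[1], x$window[2]))
  invisible(x)
}

#' Time axis of an epoch set (seconds relative to onset)
#' @param epochs an `eeg_epochs`.
#' @return numeric vector of sample times.
#' @export
epoch_times <- function(epochs) {
  epochs$window[1] + (seq_len(dim(epochs$data)[3]) - 1) / epochs$fs
}

#' Re-reference to averaged mastoids
#'
#' Subtracts the mean of the two mastoid channels from every channel.
#'
#' @param recording an `eeg_recording`.
#' @param mastoid_labels the two mastoid channel labels.
#' @return re-referenced `eeg_recording`.
#' @export
rereference_mastoids <- function(recording, mastoid_labels = c("M1", "M2")) {
  if (length(mastoid_labels) != 2) stopf("need exactly two mastoid labels")
  i <- vapply(mastoid_labels, function(ch) match_channel(recording$channels, ch), 0L)
  ref <- colMeans(recording$data[i, , drop = FALSE])
  recording$data <- sweep(recording$data, 2, ref)
  recording$reference <- paste0("avg(", paste(mastoid_labels, collapse = ","), ")")
  recording
}

# zero-phase band-pass of one vector: linear-phase windowed-sinc (Hamming)
# FIR applied by FFT convolution with the group delay compensated exactly.
# Transition widths are 25% of each corner frequency, bounded to [2 Hz,
# corner] at the low edge and by the headroom to Nyquist at the high edge.
# An FIR is used because narrowband IIR band-passes at sleep-EEG sampling
# rates are numerically unstable in direct-form filtering, and its flat
# passband preserves in-band event amplitudes.
filter_band <- function(x, fs, low, high) {
  nyq <- fs / 2
  tl <- min(max(low * 0.25, 2), low)
  th <- min(max(high * 0.25, 2), nyq - high)
  trans <- min(tl, th)
  n <- ceiling(3.3 / trans * fs)
  if (n %% 2 == 1) n <- n + 1                 # even order -> odd, symmetric
  b <- signal::fir1(n, c(low, high) / nyq, type = "pass")
  y <- signal::fftfilt(b, c(x, numeric(n)))
  y[(n / 2 + 1):(n / 2 + length(x))]
}

#' Zero-phase band-pass filter
#'
#' Applies a zero-phase band-pass to every channel, realized as a
#' linear-phase windowed-sinc (Hamming) FIR whose group delay is compensated
#' exactly. Passband sinusoids are preserved in amplitude (within ~2%) and
#' phase (zero lag); DC and out-of-band components are strongly attenuated.
#'
#' @param recording an `eeg_recording`.
#' @param low_hz high-pass corner in Hz (> 0).
#' @param high_hz low-pass corner in Hz (< fs/2).
#' @return filtered `eeg_recording`.
#' @export
bandpass <- function(recording, low_hz, high_hz) {
  fs <- recording$fs
  if (!is_scalar_num(low_hz) || !is_scalar_num(high_hz) ||
      low_hz <= 0 || high_hz <= low_hz || high_hz >= fs / 2) {
    stopf("invalid band: need 0 < low (%s) < high (%s) < fs/2 (%s)",
          low_hz, high_hz, fs / 2)
  }
  out <- recording
  for (i in seq_len(nrow(out$data))) {
    out$data[i, ] <- filter_band(out$data[i, ], fs, low_hz, high_hz)
  }
  out
}

#' Segment a recording into event-locked epochs
#'
#' Cuts one epoch per event over the half-open window `[t_min, t_max)`
#' relative to the event onset. Events whose window does not fit inside the
#' recording are dropped with a warning. Each channel of each epoch is
#' demeaned and linearly detrended unless `detrend = FALSE`.
#'
#' @param recording an `eeg_recording`.
#' @param events an `event_set`.
#' @param window numeric length-2 `(t_min, t_max)` in seconds.
#' @param detrend demean + linear detrend per channel (default TRUE).
#' @return an `eeg_epochs`.
#' @export
epoch_recording <- function(recording, events, window, detrend = TRUE) {
  fs <- recording$fs
  n_samp <- round((window[2] - window[1]) * fs)
  if (n_samp < 2) stopf("epoch window too short")
  start_idx <- round((events$onset + window[1]) * fs) + 1
  ok <- start_idx >= 1 & (start_idx + n_samp - 1) <= ncol(recording$data)
  if (any(!ok)) warnf("%d epoch(s) dropped: window outside recording", sum(!ok))
  if (!any(ok)) stopf("no epochs retained")
  starts <- start_idx[ok]
  n_ep <- length(starts)
  n_ch <- nrow(recording$data)
  arr <- array(0, c(n_ep, n_ch, n_samp))
  for (e in seq_len(n_ep)) {
    seg <- recording$data[, starts[e]:(starts[e] + n_samp - 1), drop = FALSE]
    if (detrend) seg <- t(apply(seg, 1, detrend_linear))
    arr[e, , ] <- seg
  }
  eeg_epochs(arr, window, fs, recording$channels,
             events = as.data.frame(events)[ok, , drop = FALSE])
}

#' Automatic peak-to-peak artifact rejection
#'
#' Removes epochs whose peak-to-peak amplitude on any channel exceeds the
#' threshold — a deterministic criterion standing in for visual trial
#' inspection. The rejection log is attached as attribute `"rejection_log"`.
#'
#' @param epochs an `eeg_epochs`.
#' @param ptp_threshold_uv peak-to-peak threshold in microvolts (> 0).
#' @return filtered `eeg_epochs` (errors if all epochs would be rejected).
#' @export
reject_artifacts <- function(epochs, ptp_threshold_uv) {
  if (!is_scalar_num(ptp_threshold_uv) || ptp_threshold_uv <= 0) {
    stopf("`ptp_threshold_uv` must be positive")
  }
  ptp <- apply(epochs$data, 1, function(ep) {
    max(apply(ep, 1, function(ch) diff(range(ch))))
  })
  keep <- ptp <= ptp_threshold_uv
  if (!any(keep)) stopf("all %d epochs exceed %g uV peak-to-peak",
                        length(keep), ptp_threshold_uv)
  log <- data.frame(epoch = seq_along(ptp), max_ptp_uv = ptp, rejected = !keep)
  out <- epochs
  out$data <- epochs$data[keep, , , drop = FALSE]
  if (!is.null(epochs$events)) out$events <- epochs$events[keep, , drop = FALSE]
  attr(out, "rejection_log") <- log
  out
}
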