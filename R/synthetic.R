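#' Generate 1/f-shaped background EEG
#'
#' Produces NREM-like background activity as Gaussian noise whose power
#' spectrum follows 1/f^beta, independently per channel, scaled to a target
#' standard deviation in microvolts. All generators in this module are pure
#' functions of their seed.
#'
#' @param duration_s recording duration in seconds (> 0).
#' @param fs sampling rate in Hz (default 500, the acquisition rate the
#'   pipeline assumes).
#' @param n_channels number of channels (default the 19-channel montage).
#' @param spectral_exponent beta of the 1/f^beta spectral shape (default 2,
#'   a typical NREM slope).
#' @param amplitude_scale target per-channel standard deviation in uV
#'   (0 gives an all-zero recording).
#' @param seed integer RNG seed.
#' @param channels channel labels (default the 10-10 montage, recycled or
#'   truncated to `n_channels`).
#' @return an `eeg_recording`.
#' @export
generate_background <- function(duration_s, fs = 500, n_channels = 19,
                                spectral_exponent = 2, amplitude_scale = 20,
                                seed = 1, channels = NULL) {
  if (!is_scalar_num(duration_s) || duration_s <= 0) {
    stopf("`duration_s` must be positive")
  }
  if (is.null(channels)) {
    base <- montage_1010()$label
    channels <- if (n_channels <= length(base)) base[seq_len(n_channels)] else
      c(base, paste0("X", seq_len(n_channels - length(base))))
  }
  n <- round(duration_s * fs)
  gen <- function() {
    freqs <- c(0, seq_len(n - 1))
    freqs <- pmin(freqs, n - freqs) * fs / n     # two-sided frequency axis
    shape <- c(0, freqs[-1]^(-spectral_exponent / 2))
    data <- matrix(0, n_channels, n)
    for (i in seq_len(n_channels)) {
      white <- stats::rnorm(n)
      x <- Re(stats::fft(stats::fft(white) * shape, inverse = TRUE)) / n
      s <- stats::sd(x)
      data[i, ] <- if (s > 0) x / s * amplitude_scale else x
    }
    data
  }
  data <- if (is.null(seed)) gen() else withr::with_seed(as.integer(seed), gen())
  eeg_recording(data, fs, channels, reference = "synthetic")
}

#' Generate a cue train with jittered inter-stimulus intervals
#'
#' Onsets of auditory reactivation cues with successive ISIs drawn uniformly
#' from `[isi_mean - isi_jitter, isi_mean + isi_jitter]` (the 8 +/- 2 s
#' presentation regime).
#'
#' @param n_cues number of cues (>= 1).
#' @param isi_mean mean inter-stimulus interval in seconds.
#' @param isi_jitter half-width of the uniform ISI jitter (< isi_mean).
#' @param t_start onset of the first cue in seconds.
#' @param condition condition label stored on every cue.
#' @param seed integer RNG seed.
#' @return an `event_set` with `presentation` as the running cue count.
#' @export
generate_cue_events <- function(n_cues, isi_mean = 8, isi_jitter = 2,
                                t_start = 30, condition = "high_pp", seed = 1) {
  if (!is_scalar_num(n_cues) || n_cues < 1) stopf("`n_cues` must be >= 1")
  if (isi_jitter >= isi_mean) stopf("`isi_jitter` must be smaller than `isi_mean`")
  gen <- function() {
    if (n_cues == 1) return(t_start)
    isi <- stats::runif(n_cues - 1, isi_mean - isi_jitter, isi_mean + isi_jitter)
    t_start + c(0, cumsum(isi))
  }
  onsets <- if (is.null(seed)) gen() else withr::with_seed(as.integer(seed), gen())
  event_set(onsets, condition = condition, word_id = seq_len(n_cues),
            presentation = seq_len(n_cues))
}

# closed-form slow-wave waveform: one period of a biphasic raised-cosine
# cycle (negative half-wave then positive half-wave), trough at `0`,
# trough-to-posterior-peak amplitude `amplitude`.
sw_waveform <- function(t_rel, amplitude, freq_hz) {
  Tp <- 1 / freq_hz
  out <- numeric(length(t_rel))
  inside <- t_rel >= -Tp / 4 & t_rel < 3 * Tp / 4
  out[inside] <- -(amplitude / 2) * sin(2 * pi * freq_hz * (t_rel[inside] + Tp / 4))
  out
}

#' Inject slow waves into a recording
#'
#' Adds one biphasic slow-wave cycle (negative half-wave followed by a
#' positive half-wave, one raised-cosine period at `freq_hz`) per requested
#' trough, on every channel (or the channels given). The trough occurs at the
#' stated time and the trough-to-posterior-peak amplitude of the raw waveform
#' equals the stated amplitude. Injection is additive.
#'
#' @param recording an `eeg_recording`.
#' @param trough_times trough times in seconds.
#' @param amplitudes trough-to-posterior-peak amplitudes in uV (recycled).
#' @param freq_hz slow-wave frequency in Hz (default 0.75).
#' @param channels channel labels to inject into (default: all).
#' @return list with elements `recording` (modified) and `ground_truth`
#'   (data.frame `trough_time`, `amplitude`, `freq_hz`).
#' @export
inject_slow_waves <- function(recording, trough_times, amplitudes,
                              freq_hz = 0.75, channels = NULL) {
  Tp <- 1 / freq_hz
  dur <- recording_duration(recording)
  amplitudes <- rep_len(amplitudes, length(trough_times))
  if (any(trough_times - Tp / 4 < 0 | trough_times + 3 * Tp / 4 > dur)) {
    stopf("slow-wave waveform does not fit inside the recording")
  }
  if (length(trough_times) > 1) {
    o <- order(trough_times)
    if (any(diff(trough_times[o]) < Tp)) {
      warnf("overlapping slow-wave injections are summed")
    }
  }
  rows <- if (is.null(channels)) seq_len(nrow(recording$data)) else
    vapply(channels, function(ch) match_channel(recording$channels, ch), 0L)
  t_axis <- (seq_len(ncol(recording$data)) - 1) / recording$fs
  for (k in seq_along(trough_times)) {
    if (amplitudes[k] == 0) next
    lo <- max(1L, floor((trough_times[k] - Tp / 4) * recording$fs))
    hi <- min(ncol(recording$data), ceiling((trough_times[k] + 3 * Tp / 4) * recording$fs) + 1L)
    w <- sw_waveform(t_axis[lo:hi] - trough_times[k], amplitudes[k], freq_hz)
    recording$data[rows, lo:hi] <- recording$data[rows, lo:hi] +
      matrix(w, length(rows), length(w), byrow = TRUE)
  }
  gt <- data.frame(trough_time = as.numeric(trough_times),
                   amplitude = amplitudes, freq_hz = freq_hz)
  list(recording = recording, ground_truth = gt)
}

#' Inject sleep-spindle bursts into a recording
#'
#' Adds Hann-windowed sinusoidal bursts in the fast-spindle band. When
#' `coupled_to` slow-wave trough times are given together with `lags`, the
#' envelope peak of each burst is placed at `trough + lag` (the up-state
#' coupling window being 0.3-0.8 s).
#'
#' @param recording an `eeg_recording`.
#' @param onsets burst onset times in seconds (ignored when `coupled_to`
#'   is given).
#' @param durations burst durations in seconds (recycled).
#' @param center_freqs burst frequencies in Hz (default 13; values outside
#'   12-16 Hz warn but are still injected).
#' @param amplitudes envelope peak amplitudes in uV (recycled).
#' @param coupled_to optional vector of slow-wave trough times.
#' @param lags lags in seconds of envelope peak after each trough (recycled;
#'   default 0.55).
#' @param channels channel labels to inject into (default: all).
#' @return list with `recording` and `ground_truth` (data.frame `onset`,
#'   `duration`, `peak_time`, `amplitude`, `center_freq`, `lag`).
#' @export
inject_spindles <- function(recording, onsets = NULL, durations = 1,
                            center_freqs = 13, amplitudes = 20,
                            coupled_to = NULL, lags = 0.55, channels = NULL) {
  if (!is.null(coupled_to)) {
    lags <- rep_len(lags, length(coupled_to))
    durations <- rep_len(durations, length(coupled_to))
    peak_times <- coupled_to + lags
    onsets <- peak_times - durations / 2
  } else {
    if (is.null(onsets)) stopf("give either `onsets` or `coupled_to`")
    durations <- rep_len(durations, length(onsets))
    peak_times <- onsets + durations / 2
    lags <- rep_len(NA_real_, length(onsets))
  }
  n_ev <- length(onsets)
  center_freqs <- rep_len(center_freqs, n_ev)
  amplitudes <- rep_len(amplitudes, n_ev)
  if (any(durations <= 0) || any(durations >= recording_duration(recording))) {
    stopf("spindle durations must be in (0, recording length)")
  }
  if (any(center_freqs < 12 | center_freqs > 16)) {
    warnf("center frequency outside the 12-16 Hz fast-spindle band")
  }
  if (any(onsets < 0 | onsets + durations > recording_duration(recording))) {
    stopf("spindle burst does not fit inside the recording")
  }
  rows <- if (is.null(channels)) seq_len(nrow(recording$data)) else
    vapply(channels, function(ch) match_channel(recording$channels, ch), 0L)
  fs <- recording$fs
  for (k in seq_len(n_ev)) {
    if (amplitudes[k] == 0) next
    lo <- floor(onsets[k] * fs) + 1L
    hi <- min(ncol(recording$data), lo + round(durations[k] * fs) - 1L)
    tt <- ((lo:hi) - 1) / fs - onsets[k]
    hann <- 0.5 * (1 - cos(2 * pi * tt / durations[k]))
    burst <- amplitudes[k] * hann * sin(2 * pi * center_freqs[k] * tt)
    recording$data[rows, lo:hi] <- recording$data[rows, lo:hi] +
      matrix(burst, length(rows), length(burst), byrow = TRUE)
  }
  gt <- data.frame(onset = as.numeric(onsets), duration = durations,
                   peak_time = peak_times, amplitude = amplitudes,
                   center_freq = center_freqs, lag = lags)
  list(recording = recording, ground_truth = gt)
}
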