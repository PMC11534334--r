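#' Classify spindles as slow-wave coupled or uncoupled
#'
#' A spindle is coupled when its amplitude peak falls inside the slow-wave
#' up-state window, i.e. within `[trough + 0.3, trough + 0.8]` seconds of at
#' least one slow-wave trough (closed interval: boundary hits count). A
#' spindle qualifying for several slow waves is counted once, attached to
#' the slow wave whose lag is nearest the window centre (0.55 s).
#'
#' @param spindles a `spindle_events` data.frame (uses `peak_time`).
#' @param sw_events an `sw_events` data.frame (uses `trough_time`), on the
#'   same time base as `spindles`.
#' @param window coupling window in seconds after the trough
#'   (default `c(0.3, 0.8)`).
#' @return data.frame: the spindle table plus `coupled` (logical), `sw_index`
#'   (row of the matched slow wave or NA) and `lag` (peak minus trough, NA
#'   when uncoupled).
#' @export
classify_coupling <- function(spindles, sw_events, window = c(0.3, 0.8)) {
  n <- nrow(spindles)
  out <- as.data.frame(spindles)
  out$coupled <- logical(n)
  out$sw_index <- rep(NA_integer_, n)
  out$lag <- rep(NA_real_, n)
  if (n == 0 || nrow(sw_events) == 0) return(out)
  troughs <- sw_events$trough_time
  mid <- mean(window)
  ord <- order(troughs)
  ts <- troughs[ord]
  for (k in seq_len(n)) {
    pk <- spindles$peak_time[k]
    # troughs with lag in [window]: trough in [pk - w2, pk - w1]
    lo <- findInterval(pk - window[2], ts, left.open = TRUE) + 1L
    hi <- findInterval(pk - window[1], ts)
    if (hi < lo) next
    cand <- ts[lo:hi]
    lags <- pk - cand
    best <- which.min(abs(lags - mid))
    out$coupled[k] <- TRUE
    out$sw_index[k] <- ord[lo + best - 1L]
    out$lag[k] <- lags[best]
  }
  out
}

#' Slow-wave-trough-locked time-frequency power
#'
#' Cuts segments around each slow-wave trough, computes the trial-averaged
#' Morlet TFR (7 cycles), and subtracts the mean power of the pre-trough
#' baseline (default -2 to -1.5 s). Segments are cut wider than the output
#' window so every output time is free of wavelet edge effects at the lowest
#' frequency; troughs too close to the recording edges for the padded
#' segment are dropped.
#'
#' @param recording an `eeg_recording` (unfiltered broadband signal).
#' @param sw_troughs trough times in seconds (typically the top-30%
#'   amplitude selection).
#' @param channels channels to analyze (default `"Pz"`).
#' @param halfwidth output half-window in seconds (default 2).
#' @param freqs frequency grid in Hz (default `seq(1, 30, by = 0.2)`).
#' @param n_cycles wavelet cycles (default 7).
#' @param t_step output time step in seconds (default 0.010).
#' @param baseline baseline window relative to the trough
#'   (default `c(-2, -1.5)`).
#' @return an `eeg_tfr` with times in seconds relative to the trough.
#' @export
sw_locked_tfr <- function(recording, sw_troughs, channels = "Pz",
                          halfwidth = 2.0, freqs = seq(1, 30, by = 0.2),
                          n_cycles = 7, t_step = 0.010,
                          baseline = c(-2.0, -1.5)) {
  if (length(sw_troughs) == 0) stopf("no slow-wave troughs supplied")
  pad <- 2.5 * n_cycles / (2 * pi * min(freqs)) + 0.1
  dur <- recording_duration(recording)
  ok <- (sw_troughs - halfwidth - pad) >= 0 &
    (sw_troughs + halfwidth + pad) <= dur
  if (any(!ok)) warnf("%d trough(s) too close to the recording edges dropped",
                      sum(!ok))
  if (!any(ok)) stopf("no valid troughs remain")
  ev <- event_set(sort(sw_troughs[ok]))
  eps <- epoch_recording(recording, ev,
                         window = c(-halfwidth - pad, halfwidth + pad),
                         detrend = FALSE)
  tfr <- morlet_tfr(eps, freqs = freqs, n_cycles = n_cycles, t_step = t_step,
                    channels = channels)
  keep <- tfr$times >= -halfwidth & tfr$times <= halfwidth
  tfr$power <- tfr$power[, , keep, drop = FALSE]
  tfr$times <- tfr$times[keep]
  baseline_subtract(tfr, baseline)
}

#' Mean up-state spindle-band power
#'
#' Mean baseline-corrected power in the up-state box: 11-14 Hz, 0.3-0.8 s
#' after the slow-wave trough, merged over the given channels — the
#' per-subject summary entering group statistics and correlations.
#'
#' @param tfr an `eeg_tfr` from [sw_locked_tfr()].
#' @param band frequency band in Hz (default `c(11, 14)`).
#' @param window time window in seconds after the trough
#'   (default `c(0.3, 0.8)`).
#' @param channels channels to merge.
#' @return scalar mean power.
#' @export
upstate_band_power <- function(tfr, band = c(11, 14), window = c(0.3, 0.8),
                               channels = "Pz") {
  band_window_power(tfr, band = band, window = window, channels = channels)
}

#' Per-subject mean spindle amplitude by coupling class
#'
#' Averages the spindle amplitude within each coupling class (coupled vs
#' uncoupled) per subject. Subjects lacking a class yield no row for it
#' (missing cell, not zero).
#'
#' @param coupling data.frame from [classify_coupling()] with an added
#'   `subject` column.
#' @return data.frame with `subject`, `coupled`, `mean_amplitude`, `n`.
#' @export
coupled_amplitude_contrast <- function(coupling) {
  if (!"subject" %in% names(coupling)) stopf("`coupling` needs a `subject` column")
  cells <- split(coupling, list(coupling$subject, coupling$coupled), drop = TRUE)
  rows <- lapply(cells, function(cell) {
    data.frame(subject = cell$subject[1], coupled = cell$coupled[1],
               mean_amplitude = mean(cell$amplitude), n = nrow(cell),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$subject, out$coupled), , drop = FALSE]
  rownames(out) <- NULL
  out
}
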