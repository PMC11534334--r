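#' Time-frequency representation container
#'
#' Trial-averaged oscillatory power as a `channels x freqs x times` array in
#' microvolts-squared, with its frequency and time grids and baseline
#' metadata. Cells closer to an epoch edge than 2.5 wavelet standard
#' deviations are `NA` (flagged invalid) rather than silently zero-padded.
#'
#' @param power numeric array channels x freqs x times.
#' @param freqs frequency grid in Hz (strictly increasing).
#' @param times time grid in seconds (strictly increasing).
#' @param channels channel labels.
#' @param baseline_mode `"none"` or `"absolute_subtract"`.
#' @param baseline_window baseline window (length-2) or NULL.
#' @return object of class `eeg_tfr`.
#' @export
eeg_tfr <- function(power, freqs, times, channels,
                    baseline_mode = "none", baseline_window = NULL) {
  stopifnot(length(dim(power)) == 3)
  if (any(diff(freqs) <= 0) || (length(times) > 1 && any(diff(times) <= 0))) {
    stopf("frequency and time grids must be strictly increasing")
  }
  if (baseline_mode == "none" && any(power < 0, na.rm = TRUE)) {
    stopf("raw power must be non-negative")
  }
  structure(list(power = power, freqs = as.numeric(freqs),
                 times = as.numeric(times), channels = as.character(channels),
                 baseline_mode = baseline_mode,
                 baseline_window = baseline_window),
            class = "eeg_tfr")
}

#' @export
print.eeg_tfr <- function(x, ...) {
  cat(sprintf("<eeg_tfr> %d ch x %d freqs (%g-%g Hz) x %d times (%g-%g s), baseline: %s\n",
              length(x$channels), length(x$freqs), min(x$freqs), max(x$freqs),
              length(x$times), min(x$times), max(x$times), x$baseline_mode))
  invisible(x)
}

# complex Morlet convolution of one signal at all freqs via FFT; returns
# freqs x n matrix of complex amplitude estimates (tone of amplitude a at
# frequency f yields modulus a at f).
morlet_convolve <- function(x, fs, freqs, n_cycles) {
  n <- length(x)
  nfft <- stats::nextn(2 * n, 2)
  X <- stats::fft(c(x, numeric(nfft - n)))
  out <- matrix(0i, length(freqs), n)
  for (fi in seq_along(freqs)) {
    f <- freqs[fi]
    sigma_t <- n_cycles / (2 * pi * f)
    half <- ceiling(3.5 * sigma_t * fs)
    tw <- (-half:half) / fs
    g <- exp(-tw^2 / (2 * sigma_t^2))
    w <- g * exp(2i * pi * f * tw) * (2 / sum(g))   # unit gain for a pure tone
    nw <- length(w)
    W <- stats::fft(c(w, complex(real = numeric(nfft - nw))))
    conv <- stats::fft(X * W, inverse = TRUE) / nfft
    out[fi, ] <- conv[half + seq_len(n)]            # center-aligned
  }
  out
}

#' Morlet-wavelet time-frequency power of epoched data
#'
#' Convolves each epoch and channel with complex Morlet wavelets (fixed
#' number of cycles) and averages power over epochs. Power is calibrated so
#' a pure sinusoid of amplitude a yields a^2 at its frequency. Times closer
#' than 2.5 wavelet standard deviations to an epoch edge are returned as
#' `NA` (invalid) at that frequency.
#'
#' @param epochs an `eeg_epochs`.
#' @param freqs frequency grid in Hz (all < fs/2); the wake-analysis
#'   convention is `seq(1, 45, by = 0.2)`.
#' @param n_cycles wavelet cycles (default 7).
#' @param t_step output time step in seconds (default 0.010).
#' @param channels optional subset of channels to analyze.
#' @return an `eeg_tfr` (trial-averaged, baseline mode `"none"`).
#' @export
morlet_tfr <- function(epochs, freqs = seq(1, 45, by = 0.2), n_cycles = 7,
                       t_step = 0.010, channels = NULL) {
  fs <- epochs$fs
  if (any(freqs >= fs / 2)) stopf("frequencies must be below Nyquist (%g Hz)", fs / 2)
  if (any(freqs <= 0)) stopf("frequencies must be positive")
  if (is.null(channels)) channels <- epochs$channels
  chi <- vapply(channels, function(ch) match_channel(epochs$channels, ch), 0L)
  t_in <- epoch_times(epochs)
  keep <- seq(1, length(t_in), by = max(1L, round(t_step * fs)))
  times <- t_in[keep]
  n_ep <- dim(epochs$data)[1]
  pow <- array(0, c(length(chi), length(freqs), length(times)))
  for (ci in seq_along(chi)) {
    acc <- matrix(0, length(freqs), length(times))
    for (e in seq_len(n_ep)) {
      amp <- morlet_convolve(epochs$data[e, chi[ci], ], fs, freqs, n_cycles)
      acc <- acc + Mod(amp[, keep, drop = FALSE])^2
    }
    pow[ci, , ] <- acc / n_ep
  }
  # flag edge-contaminated cells invalid
  edge_lo <- t_in[1]
  edge_hi <- t_in[length(t_in)]
  for (fi in seq_along(freqs)) {
    sigma_t <- n_cycles / (2 * pi * freqs[fi])
    bad <- times < edge_lo + 2.5 * sigma_t | times > edge_hi - 2.5 * sigma_t
    if (any(bad)) pow[, fi, bad] <- NA_real_
  }
  eeg_tfr(pow, freqs, times, channels)
}

#' Absolute baseline subtraction
#'
#' Per channel and frequency, subtracts the mean power over the baseline
#' window, giving "absolute change" values relative to the pre-stimulus
#' interval (default -1 to -0.1 s).
#'
#' @param tfr an `eeg_tfr`.
#' @param window baseline window `(t0, t1)` in seconds, within the time grid.
#' @return baseline-corrected `eeg_tfr`.
#' @export
baseline_subtract <- function(tfr, window = c(-1.0, -0.1)) {
  sel <- tfr$times >= window[1] & tfr$times <= window[2]
  if (!any(sel)) stopf("baseline window [%g, %g] is outside the time grid",
                       window[1], window[2])
  for (ci in seq_along(tfr$channels)) {
    base <- apply(tfr$power[ci, , sel, drop = FALSE], 2, mean, na.rm = TRUE)
    tfr$power[ci, , ] <- tfr$power[ci, , ] - base
  }
  tfr$baseline_mode <- "absolute_subtract"
  tfr$baseline_window <- window
  tfr
}

#' Mean power in a channel x frequency x time box
#'
#' @param tfr an `eeg_tfr`.
#' @param band frequency band `(f0, f1)` in Hz (default the 8-13 Hz alpha
#'   band).
#' @param window time window `(t0, t1)` in seconds (default 0.7-1.9 s).
#' @param channels channels to merge (default `c("Pz", "Cz")`).
#' @return scalar mean power over the selected box (`NA` cells excluded).
#' @export
band_window_power <- function(tfr, band = c(8, 13), window = c(0.7, 1.9),
                              channels = c("Pz", "Cz")) {
  if (length(channels) == 0) stopf("empty channel selection")
  chi <- vapply(channels, function(ch) match_channel(tfr$channels, ch), 0L)
  fsel <- tfr$freqs >= band[1] & tfr$freqs <= band[2]
  tsel <- tfr$times >= window[1] & tfr$times <= window[2]
  if (!any(fsel) || !any(tsel)) stopf("empty frequency/time selection")
  vals <- tfr$power[chi, fsel, tsel, drop = FALSE]
  if (all(is.na(vals))) stopf("selection contains only invalid (edge) cells")
  mean(vals, na.rm = TRUE)
}

#' Power change relative to the first presentation
#'
#' Subtracts the first-presentation TFR from the later presentations,
#' the first (naive) presentation serving as the reference condition.
#'
#' @param tfr_by_presentation list of `eeg_tfr`, indexed by presentation
#'   1..3 on identical grids.
#' @return list with elements `"2"` and `"3"`: difference `eeg_tfr`s.
#' @export
presentation_contrast <- function(tfr_by_presentation) {
  if (length(tfr_by_presentation) < 3) stopf("need presentations 1-3")
  ref <- tfr_by_presentation[[1]]
  out <- lapply(2:3, function(k) {
    tfr <- tfr_by_presentation[[k]]
    if (!identical(dim(tfr$power), dim(ref$power))) {
      stopf("presentation %d TFR has mismatched dimensions", k)
    }
    tfr$power <- tfr$power - ref$power
    tfr$baseline_mode <- "presentation_contrast"
    tfr
  })
  names(out) <- c("2", "3")
  out
}
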