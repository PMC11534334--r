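# Shared oracles and fixture builders. Everything here is deliberately
# written along a different computational path than the package code it
# checks (direct convolution instead of FFT filtering, double loops instead
# of interval searches), so tests compare two independent routes.

# independent zero-phase band-pass: hand-built Hamming windowed-sinc
# convolved in the time domain, normalized to unit gain at band center.
oracle_bandpass <- function(x, fs, lo, hi, n_taps) {
  k <- -(n_taps / 2):(n_taps / 2)
  snc <- function(v) ifelse(v == 0, 1, sin(pi * v) / (pi * v))
  h <- 2 * hi / fs * snc(2 * hi / fs * k) - 2 * lo / fs * snc(2 * lo / fs * k)
  h <- h * (0.54 + 0.46 * cos(2 * pi * k / n_taps))
  fc <- (lo + hi) / 2
  h <- h / Mod(sum(h * exp(-2i * pi * fc * k / fs)))
  y <- stats::convolve(c(numeric(n_taps), x, numeric(n_taps)), rev(h),
                       type = "filter")
  half <- (length(y) - length(x)) %/% 2
  y[half + seq_along(x)]
}

# brute-force coupling oracle: full double loop over all (spindle, SW) pairs
oracle_coupling <- function(peaks, troughs, window = c(0.3, 0.8)) {
  coupled <- logical(length(peaks))
  sw_index <- rep(NA_integer_, length(peaks))
  lag <- rep(NA_real_, length(peaks))
  mid <- mean(window)
  for (i in seq_along(peaks)) {
    best <- NA_integer_
    best_d <- Inf
    for (j in seq_along(troughs)) {
      lg <- peaks[i] - troughs[j]
      if (lg >= window[1] && lg <= window[2] && abs(lg - mid) < best_d) {
        best <- j
        best_d <- abs(lg - mid)
      }
    }
    if (!is.na(best)) {
      coupled[i] <- TRUE
      sw_index[i] <- best
      lag[i] <- peaks[i] - troughs[best]
    }
  }
  list(coupled = coupled, sw_index = sw_index, lag = lag)
}

# spindle-test fixture: bursts at the cueing cadence with envelope SNR
# defined against the mean background envelope in the spindle band
make_spindle_fixture <- function(seed, n_bursts = 20, duration = 1,
                                 snr = 5, fs = 500) {
  rec <- generate_background(200, fs = fs, n_channels = 1, channels = "Pz",
                             amplitude_scale = 15, seed = seed)
  xb <- tmrsleep:::filter_band(rec$data[1, ], fs, 12, 16)
  amp <- snr * mean(Mod(analytic_signal(xb)))
  onsets <- seq(10, 181, by = 9)[seq_len(n_bursts)]
  inj <- inject_spindles(rec, onsets = onsets, durations = duration,
                         amplitudes = amp)
  list(recording = inj$recording, onsets = onsets, duration = duration,
       amplitude = amp, fs = fs)
}

# slow-wave test fixture: one cue-locked wave per cue at trough-to-peak
# amplitude snr x broadband background SD
make_sw_fixture <- function(seed, n_cues = 20, snr = 3, fs = 500,
                            background_sd = 20) {
  rec <- generate_background(220, fs = fs, n_channels = 1, channels = "Cz",
                             amplitude_scale = background_sd, seed = seed)
  cues <- generate_cue_events(n_cues, seed = seed + 100, t_start = 15)
  troughs <- cues$onset + 0.6
  inj <- inject_slow_waves(rec, troughs, snr * background_sd)
  list(recording = inj$recording, cues = cues, troughs = troughs)
}

# small montage subset used by the cluster tests
cluster_channels <- c("Cz", "C3", "C4", "Pz", "P3", "P4", "Fz", "O1")
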