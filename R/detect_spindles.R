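#' Detect fast sleep spindles with per-subject amplitude thresholds
#'
#' Band-pass filters one channel (default Pz) in the fast-spindle band
#' (12-16 Hz) and thresholds the instantaneous amplitude: the modulus of the
#' analytic signal smoothed with a `smooth_s`-second moving average, so that
#' single-sample envelope dips do not fragment events. The detection
#' threshold is `mean + thr_sd * SD` of this smoothed envelope, with the
#' mean and SD computed per subject over the concatenated
#' cueing windows (default -2 to 8 s around each cue; the whole recording
#' when no events are given). Candidate boundaries extend to where the
#' envelope falls below `mean + edge_sd * SD`; candidates closer than 0.1 s
#' are merged; only events with a duration of 0.5-3 s are kept. The event
#' peak is the envelope maximum, and the amplitude is the mean absolute
#' value of all positive and negative peaks of the band-passed trace within
#' the event.
#'
#' @param recording an `eeg_recording`.
#' @param events optional `event_set` of cue onsets; when given, threshold
#'   statistics use only the cueing windows and detected spindles are
#'   assigned to the cue window containing their peak.
#' @param channel detection channel (default `"Pz"`).
#' @param band spindle band in Hz (default `c(12, 16)`).
#' @param thr_sd detection threshold in envelope SDs above the mean
#'   (default 1.25).
#' @param edge_sd boundary threshold in SDs (default 0.75).
#' @param window cueing window in seconds relative to onset
#'   (default `c(-2, 8)`).
#' @param min_dur,max_dur duration gates in seconds (default 0.5 and 3).
#' @param merge_gap merge candidates separated by less than this (s).
#' @param smooth_s moving-average window applied to the envelope in seconds
#'   (default 0.2).
#' @return data.frame of class `spindle_events` with columns `start_time`,
#'   `end_time`, `peak_time`, `duration`, `amplitude`, `rel_time` (peak minus
#'   assigned cue onset), `trial`, `channel`.
#' @export
detect_spindles <- function(recording, events = NULL, channel = "Pz",
                            band = c(12, 16), thr_sd = 1.25, edge_sd = 0.75,
                            window = c(-2, 8), min_dur = 0.5, max_dur = 3,
                            merge_gap = 0.1, smooth_s = 0.2) {
  fs <- recording$fs
  x <- filter_band(get_channel(recording, channel), fs, band[1], band[2])
  env <- smooth_envelope(Mod(analytic_signal(x)), fs, smooth_s)
  t_axis <- (seq_along(x) - 1) / fs
  empty <- data.frame(start_time = numeric(0), end_time = numeric(0),
                      peak_time = numeric(0), duration = numeric(0),
                      amplitude = numeric(0), rel_time = numeric(0),
                      trial = integer(0), channel = character(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("spindle_events", "data.frame")
  if (length(x) == 0) return(empty)
  # per-subject statistics over the concatenated cueing windows
  if (!is.null(events) && nrow(events) > 0) {
    in_win <- rep(FALSE, length(x))
    for (on in events$onset) {
      lo <- max(1L, floor((on + window[1]) * fs) + 1L)
      hi <- min(length(x), ceiling((on + window[2]) * fs))
      if (lo <= hi) in_win[lo:hi] <- TRUE
    }
    m <- mean(env[in_win]); s <- stats::sd(env[in_win])
  } else {
    m <- mean(env); s <- stats::sd(env)
  }
  thr <- m + thr_sd * s
  edge <- m + edge_sd * s
  above <- env > thr
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- cbind(starts[r$values], ends[r$values])
  # extend candidates outward to the edge-threshold crossings
  below_edge <- env < edge
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]
    while (i > 1 && !below_edge[i - 1]) i <- i - 1
    j <- cand[k, 2]
    while (j < length(env) && !below_edge[j + 1]) j <- j + 1
    cand[k, ] <- c(i, j)
  }
  # merge overlapping or nearly-adjacent candidates
  cand <- cand[order(cand[, 1]), , drop = FALSE]
  merged <- cand[1, , drop = FALSE]
  if (nrow(cand) > 1) {
    for (k in 2:nrow(cand)) {
      last <- nrow(merged)
      if (cand[k, 1] - merged[last, 2] < merge_gap * fs) {
        merged[last, 2] <- max(merged[last, 2], cand[k, 2])
      } else {
        merged <- rbind(merged, cand[k, ])
      }
    }
  }
  dur <- (merged[, 2] - merged[, 1] + 1) / fs
  keep <- dur >= min_dur & dur <= max_dur
  merged <- merged[keep, , drop = FALSE]
  if (nrow(merged) == 0) return(empty)
  rows <- lapply(seq_len(nrow(merged)), function(k) {
    i <- merged[k, 1]; j <- merged[k, 2]
    pk <- i - 1L + which.max(env[i:j])
    amp <- tryCatch(spindle_amplitude(x[i:j]), error = function(e) NA_real_)
    data.frame(start_time = t_axis[i], end_time = t_axis[j],
               peak_time = t_axis[pk], duration = (j - i + 1) / fs,
               amplitude = amp, stringsAsFactors = FALSE)
  })
  sp <- do.call(rbind, rows)
  sp <- sp[!is.na(sp$amplitude), , drop = FALSE]
  sp$rel_time <- NA_real_
  sp$trial <- NA_integer_
  if (!is.null(events) && nrow(events) > 0) {
    idx <- findInterval(sp$peak_time - window[1], events$onset)
    ok <- idx >= 1
    rel <- rep(NA_real_, nrow(sp))
    rel[ok] <- sp$peak_time[ok] - events$onset[idx[ok]]
    inside <- ok & rel >= window[1] & rel <= window[2]
    sp <- sp[inside, , drop = FALSE]
    sp$rel_time <- rel[inside]
    sp$trial <- idx[inside]
  }
  sp$channel <- recording$channels[match_channel(recording$channels, channel)]
  rownames(sp) <- NULL
  class(sp) <- c("spindle_events", "data.frame")
  sp
}

#' Moving-average smoothing of an amplitude envelope
#'
#' Centered moving average over `win` seconds (odd sample count); the edge
#' samples without full support keep their unsmoothed values.
#'
#' @param env numeric envelope vector.
#' @param fs sampling rate in Hz.
#' @param win window length in seconds (0 disables smoothing).
#' @return smoothed envelope, same length.
#' @export
smooth_envelope <- function(env, fs, win = 0.2) {
  k <- round(win * fs)
  if (k <= 1) return(env)
  if (k %% 2 == 0) k <- k + 1
  sm <- as.numeric(stats::filter(env, rep(1 / k, k), sides = 2))
  na <- is.na(sm)
  sm[na] <- env[na]
  sm
}

#' Spindle amplitude from the band-passed trace
#'
#' Mean of the absolute values of all positive and negative peaks (local
#' extrema) of the 12-16 Hz filtered signal within a detected spindle.
#'
#' @param segment numeric vector: the band-passed signal between the spindle
#'   start and end samples.
#' @return amplitude in microvolts.
#' @export
spindle_amplitude <- function(segment) {
  ext <- local_extrema(segment)
  idx <- sort(c(ext$maxima, ext$minima))
  if (length(idx) == 0) stopf("degenerate spindle segment: no extrema")
  mean(abs(segment[idx]))
}

#' Cue-locked spindle density histogram
#'
#' Counts spindle peaks per bin across cueing trials (count per trial),
#' keyed on the spindle peak time relative to the cue.
#'
#' @param events a `spindle_events` with `rel_time`.
#' @param n_trials number of cueing trials (>= 1).
#' @param bin_s bin width in seconds (default 0.5).
#' @param range histogram range in seconds (default `c(-0.5, 6)`).
#' @return data.frame with `bin_start`, `bin_end`, `count`, `density`.
#' @export
spindle_density <- function(events, n_trials, bin_s = 0.5, range = c(-0.5, 6)) {
  if (!is_scalar_num(n_trials) || n_trials < 1) stopf("`n_trials` must be >= 1")
  df <- bin_counts(events$rel_time[!is.na(events$rel_time)], bin_s, range)
  df$density <- df$count / n_trials
  df
}
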