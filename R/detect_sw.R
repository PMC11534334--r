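#' Detect slow waves in cue-locked sleep EEG
#'
#' Band-pass filters one channel (default Cz) in the slow-wave band
#' (0.5-3 Hz), localizes all positive and negative peaks of the filtered
#' trace, and emits one event per negative peak that is flanked by positive
#' peaks whose spacing lies in 0.3-2 s. The event amplitude is the
#' trough-to-posterior-positive-peak difference. When a cue `events` table is
#' given, detection runs on the continuous filtered signal and each trough is
#' assigned to the most recent cue whose `search_window` (default 0-6 s after
#' onset) contains it, so no trough is counted twice even when cue windows
#' overlap.
#'
#' @param recording an `eeg_recording`.
#' @param events optional `event_set` of cue onsets.
#' @param channel detection channel (default `"Cz"`).
#' @param band slow-wave band in Hz (default `c(0.5, 3)`).
#' @param search_window window in seconds relative to cue onset
#'   (default `c(0, 6)`).
#' @param prefiltered set TRUE when `recording` already holds the band-passed
#'   trace (skips filtering).
#' @return data.frame of class `sw_events` with columns `trough_time`,
#'   `prior_peak_time`, `posterior_peak_time`, `amplitude`, `rel_time`
#'   (trough minus assigned cue onset, NA without events), `trial`, `channel`.
#' @export
detect_slow_waves <- function(recording, events = NULL, channel = "Cz",
                              band = c(0.5, 3), search_window = c(0, 6),
                              prefiltered = FALSE) {
  x <- get_channel(recording, channel)
  fs <- recording$fs
  if (!prefiltered) x <- filter_band(x, fs, band[1], band[2])
  ext <- local_extrema(x)
  empty <- data.frame(trough_time = numeric(0), prior_peak_time = numeric(0),
                      posterior_peak_time = numeric(0), amplitude = numeric(0),
                      rel_time = numeric(0), trial = integer(0),
                      channel = character(0), stringsAsFactors = FALSE)
  class(empty) <- c("sw_events", "data.frame")
  pos <- ext$maxima[x[ext$maxima] > 0]
  neg <- ext$minima[x[ext$minima] < 0]
  if (length(pos) < 2 || length(neg) == 0) return(empty)
  rows <- lapply(neg, function(tr) {
    before <- pos[pos < tr]
    after <- pos[pos > tr]
    if (!length(before) || !length(after)) return(NULL)
    p0 <- before[length(before)]
    p1 <- after[1]
    spacing <- (p1 - p0) / fs
    if (spacing < 0.3 || spacing > 2) return(NULL)
    data.frame(trough_time = (tr - 1) / fs,
               prior_peak_time = (p0 - 1) / fs,
               posterior_peak_time = (p1 - 1) / fs,
               amplitude = x[p1] - x[tr],
               stringsAsFactors = FALSE)
  })
  sw <- do.call(rbind, rows)
  if (is.null(sw)) return(empty)
  sw$rel_time <- NA_real_
  sw$trial <- NA_integer_
  if (!is.null(events) && nrow(events) > 0) {
    # most recent cue whose window contains the trough; each trough once
    idx <- findInterval(sw$trough_time - search_window[1], events$onset)
    ok <- idx >= 1
    rel <- rep(NA_real_, nrow(sw))
    rel[ok] <- sw$trough_time[ok] - events$onset[idx[ok]]
    inside <- ok & rel >= search_window[1] & rel <= search_window[2]
    sw <- sw[inside, , drop = FALSE]
    sw$rel_time <- rel[inside]
    sw$trial <- idx[inside]
  }
  sw$channel <- recording$channels[match_channel(recording$channels, channel)]
  rownames(sw) <- NULL
  class(sw) <- c("sw_events", "data.frame")
  sw
}

#' Keep the top-amplitude fraction of slow waves
#'
#' Retains the `ceiling(fraction * N)` largest-amplitude events (per subject
#' when a `subject` column is present), the per-subject individualization
#' used for all downstream coupling analyses. Ties at the cut are broken in
#' favour of the earlier trough.
#'
#' @param events an `sw_events` data.frame.
#' @param fraction fraction to keep, in (0, 1] (default 0.30).
#' @return filtered `sw_events`.
#' @export
select_top_amplitude <- function(events, fraction = 0.30) {
  if (!is_scalar_num(fraction) || fraction <= 0 || fraction > 1) {
    stopf("`fraction` must be in (0, 1]")
  }
  if (nrow(events) == 0) return(events)
  pick <- function(df) {
    k <- max(1L, ceiling(fraction * nrow(df)))
    ord <- order(-df$amplitude, df$trough_time)
    df[sort(ord[seq_len(k)]), , drop = FALSE]
  }
  out <- if ("subject" %in% names(events)) {
    do.call(rbind, lapply(split(events, events$subject), pick))
  } else {
    pick(events)
  }
  rownames(out) <- NULL
  class(out) <- c("sw_events", "data.frame")
  out
}

bin_counts <- function(times, bin_s, range) {
  edges <- seq(range[1], range[2], by = bin_s)
  counts <- vapply(seq_len(length(edges) - 1), function(b) {
    sum(times >= edges[b] & times < edges[b + 1])
  }, 0)
  data.frame(bin_start = edges[-length(edges)], bin_end = edges[-1],
             count = counts)
}

#' Cue-locked slow-wave density with baseline normalization
#'
#' Counts slow-wave troughs per 0.5-s bin across cueing trials, divides by
#' the number of trials, and expresses each bin as percent change relative
#' to the mean density over the pre-cue baseline bins.
#'
#' @param events an `sw_events` with `rel_time` (seconds relative to cue).
#' @param n_trials number of cueing trials (>= 1).
#' @param bin_s bin width in seconds (default 0.5).
#' @param range histogram range in seconds (default `c(-1.5, 3)`).
#' @param baseline baseline interval whose bins normalize the curve
#'   (default `c(-1.5, 0)`).
#' @return data.frame with `bin_start`, `bin_end`, `count`, `density`
#'   (per trial) and `pct_change`; when the baseline density is zero the
#'   percent change is undefined and returned as `NA` with a warning.
#' @export
sw_density <- function(events, n_trials, bin_s = 0.5, range = c(-1.5, 3),
                       baseline = c(-1.5, 0)) {
  if (!is_scalar_num(n_trials) || n_trials < 1) stopf("`n_trials` must be >= 1")
  if (baseline[1] < range[1] || baseline[2] > range[2]) {
    stopf("baseline bins must lie within `range`")
  }
  df <- bin_counts(events$rel_time[!is.na(events$rel_time)], bin_s, range)
  df$density <- df$count / n_trials
  base_sel <- df$bin_start >= baseline[1] & df$bin_end <= baseline[2]
  base_mean <- mean(df$density[base_sel])
  if (base_mean == 0) {
    warnf("zero baseline density: percent change undefined, returning raw densities")
    df$pct_change <- NA_real_
  } else {
    df$pct_change <- (df$density / base_mean - 1) * 100
  }
  df
}

#' Cue-locked slow-wave histogram (no baseline correction)
#'
#' @inheritParams sw_density
#' @param range histogram range (default `c(-0.5, 6)`).
#' @return data.frame with `bin_start`, `bin_end`, `count`, `density`
#'   (count per trial).
#' @export
sw_histogram <- function(events, n_trials, bin_s = 0.5, range = c(-0.5, 6)) {
  if (!is_scalar_num(n_trials) || n_trials < 1) stopf("`n_trials` must be >= 1")
  df <- bin_counts(events$rel_time[!is.na(events$rel_time)], bin_s, range)
  df$density <- df$count / n_trials
  df
}
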