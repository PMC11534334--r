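test_that("a noiseless injected slow wave is recovered at its trough", {
  fs <- 500
  rec0 <- eeg_recording(matrix(0, 1, 30 * fs), fs, "Cz")
  inj <- inject_slow_waves(rec0, trough_times = 10, amplitudes = 160)
  sw <- detect_slow_waves(inj$recording)
  expect_gt(nrow(sw), 0)
  main <- sw[which.max(sw$amplitude), ]
  expect_lt(abs(main$trough_time - 10), 0.02)
  t_axis <- (seq_len(30 * fs) - 1) / fs
  # the detector's peak picking must reproduce a brute-force global
  # trough/posterior-peak search on the filtered trace exactly
  filt <- tmrsleep:::filter_band(inj$recording$data[1, ], fs, 0.5, 3)
  tr_bf <- which.min(filt)
  amp_bf <- max(filt[tr_bf:length(filt)]) - filt[tr_bf]
  expect_equal(main$trough_time, t_axis[tr_bf])
  expect_equal(main$amplitude, amp_bf, tolerance = 1e-9)
  # cross-design filter oracle: the closed-form waveform through an
  # independently built windowed-sinc band-pass gives the same attenuated
  # amplitude within a few percent (the detection band-pass removes the
  # waveform's sub-0.5 Hz content, so the raw 160 uV is not preserved)
  w <- numeric(length(t_axis))
  Tp <- 1 / 0.75
  inside <- t_axis >= 10 - Tp / 4 & t_axis < 10 + 3 * Tp / 4
  w[inside] <- -80 * sin(2 * pi * 0.75 * (t_axis[inside] - (10 - Tp / 4)))
  wf <- oracle_bandpass(w, fs, 0.5, 3, n_taps = 3300)
  tr <- which.min(wf)
  oracle_amp <- max(wf[tr:length(wf)]) - wf[tr]
  expect_lt(abs(main$amplitude - oracle_amp) / oracle_amp, 0.05)
  expect_lt(abs(main$trough_time - t_axis[tr]), 0.01)
})

test_that("peak-spacing and polarity rules gate the emitted events", {
  fs <- 200
  t <- (0:(60 * fs - 1)) / fs
  # oscillation whose positive peaks are 4 s apart: spacing > 2 s, no event
  slow <- eeg_recording(matrix(50 * sin(2 * pi * 0.25 * t), 1), fs, "Cz")
  expect_equal(nrow(detect_slow_waves(slow, prefiltered = TRUE)), 0)
  # flat signal -> empty list
  flat <- eeg_recording(matrix(0, 1, 60 * fs), fs, "Cz")
  expect_equal(nrow(detect_slow_waves(flat)), 0)
  # 1 Hz oscillation: spacing 1 s, every cycle emitted
  osc <- eeg_recording(matrix(50 * sin(2 * pi * 1 * t), 1), fs, "Cz")
  sw <- detect_slow_waves(osc, prefiltered = TRUE)
  expect_gt(nrow(sw), 50)
  expect_true(all(abs(sw$amplitude - 100) < 1))
})

test_that("every emitted event satisfies the slow-wave invariants", {
  fx <- make_sw_fixture(seed = 21)
  sw <- detect_slow_waves(fx$recording, events = fx$cues)
  expect_gt(nrow(sw), 0)
  expect_true(all(sw$prior_peak_time < sw$trough_time))
  expect_true(all(sw$trough_time < sw$posterior_peak_time))
  spacing <- sw$posterior_peak_time - sw$prior_peak_time
  expect_true(all(spacing >= 0.3 & spacing <= 2))
  expect_true(all(sw$amplitude > 0))
  expect_true(all(sw$rel_time >= 0 & sw$rel_time <= 6))
  # troughs are unique: no event counted twice across overlapping windows
  expect_equal(anyDuplicated(sw$trough_time), 0)
})

test_that("top-amplitude selection keeps ceiling(fraction N) with tie rule", {
  ev <- data.frame(trough_time = 1:10,
                   amplitude = c(5, 9, 1, 7, 3, 8, 2, 6, 4, 10))
  top <- select_top_amplitude(ev, 0.30)
  expect_equal(nrow(top), 3)
  expect_setequal(top$amplitude, c(8, 9, 10))
  expect_gte(min(top$amplitude), max(ev$amplitude[!ev$trough_time %in% top$trough_time]))
  expect_equal(nrow(select_top_amplitude(ev, 1)), 10)
  # tie at the cut: earlier trough wins
  tie <- data.frame(trough_time = c(1, 2, 3, 4), amplitude = c(9, 5, 5, 1))
  top2 <- select_top_amplitude(tie, 0.5)
  expect_equal(top2$trough_time, c(1, 2))
  # per-subject selection
  two <- rbind(cbind(ev, subject = 1), cbind(ev, subject = 2))
  expect_equal(nrow(select_top_amplitude(two, 0.30)), 6)
  expect_error(select_top_amplitude(ev, 0), "fraction")
  expect_equal(nrow(select_top_amplitude(ev[0, ], 0.3)), 0)
})

test_that("density bins count troughs per trial with percent-change baseline", {
  # 10 troughs in one bin, 20 trials -> density 0.5 (no baseline events,
  # so the percent change is flagged undefined)
  ev <- data.frame(rel_time = rep(0.7, 10), amplitude = 1)
  expect_warning(d <- sw_density(ev, n_trials = 20), "baseline")
  expect_equal(d$density[d$bin_start == 0.5], 0.5)
  expect_equal(sum(d$count), 10)
  # baseline mean 0.2, bin 0.3 -> +50%
  ev2 <- data.frame(rel_time = c(rep(c(-1.2, -0.7, -0.2), each = 4),
                                 rep(0.2, 6)))
  d2 <- sw_density(ev2, n_trials = 20)
  expect_equal(d2$pct_change[d2$bin_start == 0], 50)
  # uniform rate -> 0% everywhere (one trough per bin)
  ev3 <- data.frame(rel_time = seq(-1.25, 2.75, by = 0.5))
  d3 <- sw_density(ev3, n_trials = 5)
  expect_true(all(abs(d3$pct_change) < 1e-9))
  # empty baseline is flagged, not divided by zero
  ev4 <- data.frame(rel_time = rep(1.2, 5))
  expect_warning(d4 <- sw_density(ev4, n_trials = 5), "baseline")
  expect_true(all(is.na(d4$pct_change)))
})

test_that("histogram conserves counts and localizes cue-locked troughs", {
  ev <- data.frame(rel_time = c(0.7, 0.71, 0.8, 2.2, 5.9, 7.5))
  h <- sw_histogram(ev, n_trials = 10)
  expect_equal(sum(h$count), 5)              # 7.5 s is outside -0.5-6
  expect_equal(h$bin_start[which.max(h$count)], 0.5)
  h0 <- sw_histogram(ev[0, , drop = FALSE], n_trials = 10)
  expect_true(all(h0$count == 0))
})

test_that("the detector recovers injected waves among background activity", {
  fx <- make_sw_fixture(seed = 1)
  sw <- detect_slow_waves(fx$recording, events = fx$cues)
  err <- vapply(fx$troughs, function(tt) min(abs(sw$trough_time - tt)), 0)
  expect_gte(mean(err <= 0.05), 0.9)
  # top-30% selection ranks the injected high-amplitude waves first
  top <- select_top_amplitude(sw, 0.30)
  hits <- vapply(fx$troughs, function(tt) any(abs(top$trough_time - tt) <= 0.05),
                 TRUE)
  expect_gte(mean(hits), 0.9)
})
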