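test_that("background generator is seed-deterministic with 1/f^beta shape", {
  a <- generate_background(10, fs = 200, n_channels = 2, seed = 5)
  b <- generate_background(10, fs = 200, n_channels = 2, seed = 5)
  expect_identical(a$data, b$data)
  expect_false(identical(a$data,
                         generate_background(10, fs = 200, n_channels = 2,
                                             seed = 6)$data))
  # amplitude_scale 0 -> all-zero recording
  z <- generate_background(5, fs = 100, n_channels = 1, amplitude_scale = 0,
                           seed = 1)
  expect_true(all(z$data == 0))
  # log-log periodogram slope ~ -beta for beta = 1
  rec <- generate_background(60, fs = 200, n_channels = 1,
                             spectral_exponent = 1, amplitude_scale = 10,
                             seed = 3)
  sp <- stats::spec.pgram(rec$data[1, ], plot = FALSE, taper = 0)
  f <- sp$freq * 200
  keep <- f > 0.5 & f < 50
  slope <- unname(coef(stats::lm(log10(sp$spec[keep]) ~ log10(f[keep])))[2])
  expect_lt(abs(slope - (-1)), 0.2)
  expect_error(generate_background(-1), "positive")
})

test_that("cue trains respect the 8 +/- 2 s ISI regime", {
  ev <- generate_cue_events(100, seed = 2)
  expect_equal(nrow(ev), 100)
  isi <- diff(ev$onset)
  expect_length(isi, 99)
  expect_true(all(isi >= 6 & isi <= 10))
  expect_equal(nrow(generate_cue_events(1, seed = 1)), 1)
  expect_identical(generate_cue_events(20, seed = 9)$onset,
                   generate_cue_events(20, seed = 9)$onset)
  expect_error(generate_cue_events(10, isi_mean = 8, isi_jitter = 8), "jitter")
})

test_that("slow-wave injection places the trough and amplitude exactly", {
  fs <- 500
  rec0 <- eeg_recording(matrix(0, 1, 30 * fs), fs, "Cz")
  inj <- inject_slow_waves(rec0, trough_times = 10, amplitudes = 160)
  x <- inj$recording$data[1, ]
  t_axis <- (seq_along(x) - 1) / fs
  # closed-form raw waveform: trough at 10 s, trough-to-posterior-peak 160
  expect_lt(abs(t_axis[which.min(x)] - 10), 1e-3)
  post <- x[t_axis >= 10]
  expect_lt(abs((max(post) - min(x)) - 160), 1)
  # amplitude 0 leaves the recording unchanged
  same <- inject_slow_waves(rec0, 10, 0)$recording
  expect_identical(same$data, rec0$data)
  # waveform must fit
  expect_error(inject_slow_waves(rec0, 0.1, 100), "fit")
  # overlapping injections warn and sum
  expect_warning(inject_slow_waves(rec0, c(10, 10.5), 100), "summed")
})

test_that("injection is additive over the background", {
  rec <- generate_background(20, fs = 200, n_channels = 1, seed = 8)
  zero <- eeg_recording(matrix(0, 1, 20 * 200), 200, rec$channels)
  a <- inject_slow_waves(rec, 10, 120)$recording$data
  b <- inject_slow_waves(zero, 10, 120)$recording$data + rec$data
  expect_equal(a, b, tolerance = 1e-12)
  s1 <- inject_spindles(rec, onsets = 5, durations = 1, amplitudes = 30)$recording$data
  s2 <- inject_spindles(zero, onsets = 5, durations = 1, amplitudes = 30)$recording$data + rec$data
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("spindle bursts carry a Hann envelope peaked at trough + lag", {
  fs <- 500
  rec0 <- eeg_recording(matrix(0, 1, 30 * fs), fs, "Pz")
  inj <- inject_spindles(rec0, durations = 1, amplitudes = 20,
                         coupled_to = 10, lags = 0.5)
  x <- inj$recording$data[1, ]
  env <- Mod(analytic_signal(x))
  t_axis <- (seq_along(x) - 1) / fs
  expect_lt(abs(t_axis[which.max(env)] - 10.5), 0.02)
  expect_lt(abs(max(env) - 20), 1)
  expect_equal(inj$ground_truth$peak_time, 10.5)
  # zero amplitude leaves data untouched
  expect_identical(inject_spindles(rec0, onsets = 5, durations = 1,
                                   amplitudes = 0)$recording$data, rec0$data)
  expect_warning(inject_spindles(rec0, onsets = 5, durations = 1,
                                 center_freqs = 11, amplitudes = 5),
                 "12-16")
  expect_error(inject_spindles(rec0, onsets = 5, durations = 0,
                               amplitudes = 5), "duration")
})

test_that("behavior generator emits the full trial structure", {
  beh <- generate_behavior(behavior_sim_params(seed = 4))
  expect_equal(nrow(beh$encoding), 480)
  expect_equal(nrow(beh$memory_pre), 160)
  expect_equal(nrow(beh$memory_post), 160)
  expect_setequal(unique(beh$encoding$condition), c("high_pp", "low_pp"))
  counts <- table(beh$encoding$condition, beh$encoding$reward_category)
  expect_true(all(counts == 120))        # 40 words x 3 presentations
  # response_type is consistent with (reward_category, response)
  with(beh$encoding, {
    expect_true(all(response_type[reward_category == "rewarded" &
                                    response == "reward_button"] == "hit"))
    expect_true(all(response_type[reward_category == "unrewarded" &
                                    response == "reward_button"] == "false_alarm"))
  })
  expect_identical(generate_behavior(behavior_sim_params(seed = 4))$encoding,
                   beh$encoding)
})

test_that("easy condition outperforms difficult by presentation 3", {
  d3 <- vapply(1:100, function(s) {
    beh <- generate_behavior(behavior_sim_params(seed = s))
    sc <- score_session(beh$encoding, by = c("condition", "presentation"))
    c(sc$dprime[sc$condition == "high_pp" & sc$presentation == 3],
      sc$dprime[sc$condition == "low_pp" & sc$presentation == 3])
  }, numeric(2))
  expect_gt(mean(d3[1, ]), mean(d3[2, ]))
})
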