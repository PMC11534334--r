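make_tone_epochs <- function(freq = 10, amp = 1, fs = 250, n_ep = 2,
                             window = c(-2, 4)) {
  dur <- 40
  t <- (0:(dur * fs - 1)) / fs
  rec <- eeg_recording(matrix(amp * sin(2 * pi * freq * t), 1), fs, "Pz")
  epoch_recording(rec, event_set(seq(10, by = 8, length.out = n_ep)),
                  window, detrend = FALSE)
}

test_that("Morlet power is calibrated, peaked at the tone, quadratic in amplitude", {
  ep <- make_tone_epochs(freq = 10, amp = 1)
  tfr <- morlet_tfr(ep, freqs = seq(5, 15, by = 0.2))
  prof <- apply(tfr$power[1, , ], 1, mean, na.rm = TRUE)
  expect_lt(abs(tfr$freqs[which.max(prof)] - 10), 0.2 + 1e-9)
  mid_t <- which.min(abs(tfr$times - 1))
  mid_f <- which.min(abs(tfr$freqs - 10))
  expect_equal(tfr$power[1, mid_f, mid_t], 1, tolerance = 0.02)
  # response decays monotonically with |f - f_tone| near the peak
  near <- which(abs(tfr$freqs - 10) <= 2)
  lower <- near[tfr$freqs[near] <= 10]
  upper <- near[tfr$freqs[near] >= 10]
  expect_true(all(diff(prof[lower]) >= -1e-9))
  expect_true(all(diff(prof[upper]) <= 1e-9))
  # doubling the amplitude quadruples power
  tfr2 <- morlet_tfr(make_tone_epochs(freq = 10, amp = 2),
                     freqs = seq(5, 15, by = 0.2))
  expect_equal(tfr2$power[1, mid_f, mid_t], 4, tolerance = 0.1)
  # zero signal -> zero power
  ep0 <- make_tone_epochs(amp = 0)
  tfr0 <- morlet_tfr(ep0, freqs = c(5, 10))
  expect_true(all(tfr0$power == 0, na.rm = TRUE))
  expect_error(morlet_tfr(ep, freqs = c(10, 130)), "Nyquist")
})

test_that("edge samples within 2.5 wavelet SDs are flagged invalid", {
  ep <- make_tone_epochs()
  tfr <- morlet_tfr(ep, freqs = c(2, 20))
  sigma2 <- 7 / (2 * pi * 2)
  bad <- tfr$times < tfr$times[1] + 2.5 * sigma2
  expect_true(all(is.na(tfr$power[1, 1, bad])))
  sigma20 <- 7 / (2 * pi * 20)
  good <- tfr$times > tfr$times[1] + 2.5 * sigma20 + 0.05 &
    tfr$times < max(tfr$times) - 2.5 * sigma20 - 0.05
  expect_true(all(!is.na(tfr$power[1, 2, good])))
})

test_that("baseline subtraction recovers power steps and is idempotent", {
  fs <- 250
  dur <- 60
  t <- (0:(dur * fs - 1)) / fs
  # 10 Hz amplitude 1 everywhere, amplitude 2 (power 4) from 0.5 s after cues
  onsets <- c(15, 30, 45)
  amp <- rep(1, length(t))
  for (o in onsets) amp[t >= o + 0.5 & t < o + 3] <- 2
  rec <- eeg_recording(matrix(amp * sin(2 * pi * 10 * t), 1), fs, "Pz")
  ep <- epoch_recording(rec, event_set(onsets), c(-2, 4), detrend = FALSE)
  tfr <- morlet_tfr(ep, freqs = seq(8, 12, by = 0.5))
  cor <- baseline_subtract(tfr, c(-1, -0.1))
  f10 <- which(cor$freqs == 10)
  t_mid <- which.min(abs(cor$times - 1.7))
  expect_equal(cor$power[1, f10, t_mid], 3, tolerance = 0.15)  # 4 - 1
  t_pre <- which.min(abs(cor$times - (-0.5)))
  expect_lt(abs(cor$power[1, f10, t_pre]), 0.1)
  # idempotent once the baseline mean is zero
  twice <- baseline_subtract(cor, c(-1, -0.1))
  expect_equal(twice$power, cor$power, tolerance = 1e-9)
  expect_error(baseline_subtract(tfr, c(-100, -90)), "outside")
})

test_that("averaging epochs before or after baseline subtraction is identical", {
  ep <- make_tone_epochs(n_ep = 3)
  # per-epoch TFRs, subtract, then average
  singles <- lapply(1:3, function(e) {
    one <- ep
    one$data <- ep$data[e, , , drop = FALSE]
    baseline_subtract(morlet_tfr(one, freqs = seq(8, 12, by = 1)),
                      c(-1, -0.1))$power
  })
  sub_then_avg <- Reduce(`+`, singles) / 3
  avg_then_sub <- baseline_subtract(morlet_tfr(ep, freqs = seq(8, 12, by = 1)),
                                    c(-1, -0.1))$power
  expect_equal(sub_then_avg, avg_then_sub, tolerance = 1e-9)
})

test_that("box averaging selects exactly the requested channels and window", {
  pow <- array(0, c(3, 5, 7))
  pow[2, , ] <- 2; pow[3, , ] <- 4
  tfr <- eeg_tfr(pow, freqs = seq(8, 12, 1), times = seq(0, 3, 0.5),
                 channels = c("Fz", "Pz", "Cz"))
  expect_equal(band_window_power(tfr, c(8, 12), c(0, 3), c("Pz", "Cz")), 3)
  expect_equal(band_window_power(tfr, c(8, 12), c(0, 3), "Fz"), 0)
  expect_error(band_window_power(tfr, c(8, 12), c(0, 3), character(0)),
               "empty")
  expect_error(band_window_power(tfr, c(50, 60), c(0, 3), "Pz"), "empty")
  # alpha injected only inside the box exceeds the outside mean
  pow2 <- array(1, c(1, 5, 7))
  pow2[1, 2:3, 3:5] <- 6
  tfr2 <- eeg_tfr(pow2, seq(8, 12, 1), seq(0, 3, 0.5), "Pz")
  expect_gt(band_window_power(tfr2, c(9, 10), c(1, 2), "Pz"),
            band_window_power(tfr2, c(11, 12), c(2.5, 3), "Pz"))
})

test_that("presentation contrasts subtract the first presentation exactly", {
  base <- array(abs(rnorm(2 * 3 * 4)), c(2, 3, 4))
  mk <- function(p) eeg_tfr(p, freqs = 1:3, times = 1:4,
                            channels = c("Pz", "Cz"))
  t1 <- mk(base); t2 <- mk(base * 2); t3 <- mk(base * 0.5)
  d <- presentation_contrast(list(t1, t2, t3))
  expect_equal(d[["2"]]$power + t1$power, t2$power)
  expect_equal(d[["3"]]$power, base * 0.5 - base)
  # identical presentations -> zero difference
  dz <- presentation_contrast(list(t1, t1, t1))
  expect_true(all(dz[["2"]]$power == 0))
  expect_error(presentation_contrast(list(t1, t2)), "need presentations")
})
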