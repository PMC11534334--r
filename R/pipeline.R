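#' Pipeline configuration
#'
#' Builds the validated configuration that drives [run_pipeline()]. Every
#' constant of the analysis (bands, windows, detector thresholds, bin
#' definitions, statistics parameters, seeds) is named here; unknown keys
#' are errors, not warnings.
#'
#' @param ... overrides of the defaults listed below.
#' @return list of class `pipeline_config`.
#' @details Default simulation regime: two cueing groups (`high_pp` cued vs
#' `low_pp` cued), 500 Hz, 19-channel montage, cue trains at 8 +/- 2 s ISI,
#' one slow wave evoked 0.4-0.9 s after each cue, coupled spindle bursts at
#' 0.3-0.8 s lag after the slow-wave trough with a group-dependent envelope
#' amplitude, plus uncoupled bursts of equal amplitude in both groups.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1,
    n_subjects_per_group = 6,
    fs = 500,
    channels = montage_1010()$label,
    n_cues = 12,
    isi_mean = 8, isi_jitter = 2, t_start = 20,
    background_exponent = 2, background_sd = 20,
    sw_delay = c(0.4, 0.9), sw_amplitude_mean = 100, sw_amplitude_sd = 15,
    coupling_prob = 0.8, coupling_lag = c(0.3, 0.8),
    spindle_duration = c(0.7, 1.2), spindle_freq = 13,
    coupled_spindle_amp = c(group1 = 14, group2 = 8),
    uncoupled_spindle_amp = 8, uncoupled_offset = c(1.5, 3),
    sleep_band = c(0.5, 35),
    # search window extended below the cue onset so the density baseline
    # bins (-1.5-0 s) can be populated; the up-state analyses use 0-6 s events
    sw_band = c(0.5, 3), sw_channel = "Cz", sw_search_window = c(-1.5, 6),
    sw_top_fraction = 0.30,
    spindle_band = c(12, 16), spindle_channel = "Pz",
    spindle_thr_sd = 1.25, spindle_edge_sd = 0.75,
    spindle_window = c(-2, 8),
    tfr_freqs = seq(5, 20, by = 0.5), tfr_halfwidth = 2,
    tfr_n_cycles = 7, tfr_t_step = 0.02, tfr_baseline = c(-2, -1.5),
    upstate_band = c(11, 14), upstate_window = c(0.3, 0.8),
    stats_channels = c("Pz", "P3", "P4"), stats_n_perm = 500,
    density_bin = 0.5, density_range = c(-1.5, 3),
    density_baseline = c(-1.5, 0),
    behavior = NULL,              # NULL -> behavior_sim_params() defaults
    out_dir = NULL
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) stopf("unknown config key(s): %s",
                             paste(unknown, collapse = ", "))
  defaults[names(over)] <- over
  structure(defaults, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file path; keys must match [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

simulate_subject <- function(cfg, group, subject) {
  seed0 <- derive_seed(cfg$seed, group * 1000L + subject)
  duration <- cfg$t_start + cfg$n_cues * (cfg$isi_mean + cfg$isi_jitter) + 20
  rec <- generate_background(duration, fs = cfg$fs,
                             n_channels = length(cfg$channels),
                             spectral_exponent = cfg$background_exponent,
                             amplitude_scale = cfg$background_sd,
                             seed = seed0, channels = cfg$channels)
  cues <- generate_cue_events(cfg$n_cues, cfg$isi_mean, cfg$isi_jitter,
                              t_start = cfg$t_start,
                              condition = if (group == 1) "high_pp" else "low_pp",
                              seed = seed0 + 1L)
  amp_coupled <- cfg$coupled_spindle_amp[[group]]
  sim <- withr::with_seed(seed0 + 2L, {
    troughs <- cues$onset + stats::runif(nrow(cues), cfg$sw_delay[1], cfg$sw_delay[2])
    sw_amps <- pmax(30, stats::rnorm(nrow(cues), cfg$sw_amplitude_mean,
                                     cfg$sw_amplitude_sd))
    coupled <- stats::runif(nrow(cues)) < cfg$coupling_prob
    lags <- stats::runif(sum(coupled), cfg$coupling_lag[1], cfg$coupling_lag[2])
    durs <- stats::runif(sum(coupled), cfg$spindle_duration[1], cfg$spindle_duration[2])
    n_unc <- max(1L, round(nrow(cues) / 2))
    unc_troughs <- sample(troughs, n_unc)
    unc_on <- unc_troughs + stats::runif(n_unc, cfg$uncoupled_offset[1],
                                         cfg$uncoupled_offset[2])
    unc_durs <- stats::runif(n_unc, cfg$spindle_duration[1], cfg$spindle_duration[2])
    list(troughs = troughs, sw_amps = sw_amps, coupled = coupled,
         lags = lags, durs = durs, unc_on = unc_on, unc_durs = unc_durs)
  })
  inj <- inject_slow_waves(rec, sim$troughs, sim$sw_amps)
  rec <- inj$recording
  if (any(sim$coupled)) {
    inj2 <- inject_spindles(rec, durations = sim$durs,
                            center_freqs = cfg$spindle_freq,
                            amplitudes = amp_coupled,
                            coupled_to = sim$troughs[sim$coupled],
                            lags = sim$lags)
    rec <- inj2$recording
  }
  inj3 <- inject_spindles(rec, onsets = sim$unc_on, durations = sim$unc_durs,
                          center_freqs = cfg$spindle_freq,
                          amplitudes = cfg$uncoupled_spindle_amp)
  rec <- inj3$recording
  list(recording = rec, cues = cues,
       ground_truth = list(sw = inj$ground_truth,
                           coupled_lags = sim$lags))
}

analyze_subject <- function(cfg, rec, cues) {
  rec_f <- bandpass(rec, cfg$sleep_band[1], cfg$sleep_band[2])
  sw <- detect_slow_waves(rec_f, events = cues, channel = cfg$sw_channel,
                          band = cfg$sw_band,
                          search_window = cfg$sw_search_window)
  sw_top <- select_top_amplitude(sw, cfg$sw_top_fraction)
  sp <- detect_spindles(rec_f, events = cues, channel = cfg$spindle_channel,
                        band = cfg$spindle_band, thr_sd = cfg$spindle_thr_sd,
                        edge_sd = cfg$spindle_edge_sd,
                        window = cfg$spindle_window)
  cpl <- classify_coupling(sp, sw_top, window = cfg$upstate_window)
  upstate <- NA_real_
  upstate_box <- NULL
  if (nrow(sw_top) > 0) {
    tfr <- tryCatch(
      sw_locked_tfr(rec_f, sw_top$trough_time, channels = cfg$stats_channels,
                    halfwidth = cfg$tfr_halfwidth, freqs = cfg$tfr_freqs,
                    n_cycles = cfg$tfr_n_cycles, t_step = cfg$tfr_t_step,
                    baseline = cfg$tfr_baseline),
      error = function(e) NULL)
    if (!is.null(tfr)) {
      upstate <- upstate_band_power(tfr, band = cfg$upstate_band,
                                    window = cfg$upstate_window,
                                    channels = cfg$spindle_channel)
      fsel <- tfr$freqs >= cfg$upstate_band[1] & tfr$freqs <= cfg$upstate_band[2]
      tsel <- tfr$times >= cfg$upstate_window[1] &
        tfr$times <= cfg$upstate_window[2]
      upstate_box <- tfr$power[, fsel, tsel, drop = FALSE]
    }
  }
  dens <- sw_density(sw_top, n_trials = nrow(cues), bin_s = cfg$density_bin,
                     range = cfg$density_range,
                     baseline = cfg$density_baseline)
  list(sw = sw, sw_top = sw_top, spindles = sp, coupling = cpl,
       upstate_power = upstate, upstate_box = upstate_box, density = dens)
}

#' Run the full simulation-and-analysis pipeline
#'
#' Simulates two cueing groups of subjects with known ground truth
#' (cue-evoked slow waves, up-state-coupled spindle bursts whose amplitude
#' depends on group, uncoupled bursts, Bernoulli discrimination behavior),
#' then runs the complete analysis: band-pass preprocessing, slow-wave
#' detection with top-30% selection, spindle detection, coupling
#' classification, slow-wave-locked time-frequency power, cue-locked
#' slow-wave density, SDT behavioral scoring, and group statistics on the
#' up-state spindle-band power.
#'
#' @param config a [pipeline_config()].
#' @return list of class `tmr_pipeline_result`: `subjects` (per-subject
#'   summary data.frame), `upstate_cluster` (the primary group inference: a
#'   cluster-based permutation test over the up-state
#'   channel x frequency x time box), `upstate_test` (post-hoc unpaired
#'   t-test on the scalar up-state power), `behavior` (per-subject overnight
#'   d' changes and the one-sample test of the cued condition), `density`
#'   (grand-average slow-wave density curve), and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- config
  rows <- list()
  powers <- list(`1` = numeric(0), `2` = numeric(0))
  boxes <- list(`1` = list(), `2` = list())
  deltas <- numeric(0)
  dens_curves <- list()
  for (g in 1:2) {
    for (s in seq_len(cfg$n_subjects_per_group)) {
      sim <- tryCatch(simulate_subject(cfg, g, s),
                      error = function(e) stopf("stage simulate failed (group %d, subject %d): %s",
                                                g, s, conditionMessage(e)))
      res <- tryCatch(analyze_subject(cfg, sim$recording, sim$cues),
                      error = function(e) stopf("stage analyze failed (group %d, subject %d): %s",
                                                g, s, conditionMessage(e)))
      beh_par <- cfg$behavior
      if (is.null(beh_par)) beh_par <- behavior_sim_params()
      beh_par$seed <- derive_seed(cfg$seed, g * 1000L + s + 500L)
      beh <- generate_behavior(beh_par)
      pre <- score_session(beh$memory_pre)
      post <- score_session(beh$memory_post)
      ch <- overnight_change(pre, post)
      cued <- if (g == 1) "high_pp" else "low_pp"
      delta_cued <- ch$delta_dprime[ch$condition == cued]
      rows[[length(rows) + 1]] <- data.frame(
        group = g, subject = s,
        n_sw = nrow(res$sw), n_sw_top = nrow(res$sw_top),
        n_spindles = nrow(res$spindles),
        n_coupled = sum(res$coupling$coupled),
        upstate_power = res$upstate_power,
        delta_dprime_cued = delta_cued)
      powers[[g]] <- c(powers[[g]], res$upstate_power)
      if (!is.null(res$upstate_box) && !anyNA(res$upstate_box)) {
        boxes[[g]] <- c(boxes[[g]], list(res$upstate_box))
      }
      deltas <- c(deltas, delta_cued)
      dens_curves[[length(dens_curves) + 1]] <- res$density$pct_change
    }
  }
  subjects <- do.call(rbind, rows)
  pa <- powers[[1]][is.finite(powers[[1]])]
  pb <- powers[[2]][is.finite(powers[[2]])]
  upstate_test <- if (length(pa) >= 2 && length(pb) >= 2) {
    ttest_effsize(pa, pb, paired = FALSE)
  } else NULL
  # primary group inference: cluster-based permutation test over the
  # up-state channel x frequency x time box, as in the sensor-level analysis
  upstate_cluster <- NULL
  if (length(boxes[[1]]) >= 2 && length(boxes[[2]]) >= 2) {
    stack <- function(lst) {
      d <- dim(lst[[1]])
      arr <- array(0, c(length(lst), d))
      for (i in seq_along(lst)) arr[i, , , ] <- lst[[i]]
      arr
    }
    upstate_cluster <- cluster_permutation_test(
      stack(boxes[[1]]), stack(boxes[[2]]), paired = FALSE,
      channels = cfg$stats_channels, n_perm = cfg$stats_n_perm,
      seed = derive_seed(cfg$seed, 999L))
  }
  behavior_test <- if (length(deltas) >= 2 && stats::sd(deltas) > 0) {
    ttest_effsize(deltas)
  } else NULL
  dens_mat <- do.call(rbind, dens_curves)
  density <- data.frame(bin_start = seq(cfg$density_range[1],
                                        cfg$density_range[2] - cfg$density_bin,
                                        by = cfg$density_bin))
  density$pct_change <- colMeans(dens_mat, na.rm = TRUE)
  manifest <- list(package = "tmrsleep",
                   version = as.character(utils::packageVersion("tmrsleep")),
                   seed = cfg$seed,
                   config = unclass(cfg)[setdiff(names(cfg), "out_dir")],
                   counts = list(subjects = nrow(subjects),
                                 sw = sum(subjects$n_sw),
                                 spindles = sum(subjects$n_spindles),
                                 coupled = sum(subjects$n_coupled)))
  out <- structure(list(subjects = subjects, upstate_test = upstate_test,
                        upstate_cluster = upstate_cluster,
                        behavior = list(delta_dprime = deltas,
                                        test = behavior_test),
                        density = density, manifest = manifest),
                   class = "tmr_pipeline_result")
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(subjects, file.path(cfg$out_dir, "subjects.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(density, file.path(cfg$out_dir, "sw_density.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' @export
print.tmr_pipeline_result <- function(x, ...) {
  cat("<tmr_pipeline_result>\n")
  cat(sprintf("  %d subjects, %d slow waves, %d spindles (%d coupled)\n",
              nrow(x$subjects), sum(x$subjects$n_sw),
              sum(x$subjects$n_spindles), sum(x$subjects$n_coupled)))
  if (!is.null(x$upstate_cluster)) {
    cl <- x$upstate_cluster$clusters
    if (nrow(cl)) {
      cat(sprintf("  up-state cluster contrast: max cluster t-sum = %.1f, p_mc = %.4f\n",
                  cl$stat[1], cl$p_mc[1]))
    } else {
      cat("  up-state cluster contrast: no suprathreshold cluster\n")
    }
  }
  if (!is.null(x$upstate_test)) {
    cat(sprintf("  up-state power group contrast: t(%g) = %.2f, p = %.4f, d = %.2f\n",
                x$upstate_test$df, x$upstate_test$t, x$upstate_test$p,
                x$upstate_test$cohen_d))
  }
  if (!is.null(x$behavior$test)) {
    cat(sprintf("  cued overnight delta-d': mean = %.3f, t(%g) = %.2f, p = %.4f\n",
                mean(x$behavior$delta_dprime), x$behavior$test$df,
                x$behavior$test$t, x$behavior$test$p))
  }
  invisible(x)
}
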