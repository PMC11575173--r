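#' Synthetic-recovery benchmarks
#'
#' Each `benchmark_*` function regenerates synthetic data with known ground
#' truth under the study conditions, runs the corresponding analysis stage
#' blind to that truth, and returns recovery metrics. They are the package's
#' validation surface: the test suite asserts on their output and the
#' acceptance script reports it.
#'
#' @name benchmarks
#' @param seed integer seed controlling every source of randomness.
NULL

#' @describeIn benchmarks PSC detector recall/precision on 100-s traces
#'   (2 Hz events, amplitude/noise-SD = 5) with +/-2 ms matching, and the
#'   false-event rate on pure noise.
#' @param n_traces number of event traces.
#' @export
benchmark_psc_detection <- function(seed = 1, n_traces = 2) {
  res <- lapply(seq_len(n_traces), function(i) {
    cfg <- psc_synth_config(duration_s = 100, fs_hz = 10000, event_rate_hz = 2,
                            amp_mean_pa = 25, amp_cv = 0.4, noise_sd_pa = 5,
                            drift_amp_pa = 10, seed = seed * 100 + i)
    sim <- gen_psc_trace(cfg)
    ev <- suppressWarnings(detect_psc(sim$trace, "sEPSC"))
    match_events(ev$onset_s, sim$truth$onset_s, tol_ms = 2)
  })
  noise <- gen_psc_trace(psc_synth_config(duration_s = 100, event_rate_hz = 0,
                                          noise_sd_pa = 5, drift_amp_pa = 10,
                                          seed = seed * 100 + 99))
  ev0 <- suppressWarnings(detect_psc(noise$trace, "sEPSC"))
  list(recall = mean(vapply(res, `[[`, 0, "recall")),
       precision = mean(vapply(res, `[[`, 0, "precision")),
       false_rate_hz = nrow(ev0) / 100,
       n_traces = n_traces)
}

#' @describeIn benchmarks burst index of a homogeneous Poisson train with
#'   about 1e5 spikes (flat-ACG expectation -7/23), plus the all-head and
#'   all-tail extremes.
#' @export
benchmark_burst_index <- function(seed = 1) {
  st <- gen_spike_train(spike_synth_config(duration_s = 5000, rate_hz = 20,
                                           refractory_ms = 0, seed = seed))
  poisson_idx <- burst_index(autocorrelogram(st))$index
  head_idx <- burst_index(autocorrelogram(seq(0, 2, by = 0.005),
                                          max_lag_ms = 12))$index
  tail_idx <- burst_index(autocorrelogram(seq(0, 4, by = 0.040)))$index
  list(poisson_index = poisson_idx, head_only_index = head_idx,
       tail_only_index = tail_idx, n_spikes = length(st))
}

#' @describeIn benchmarks bootstrap calibration (false-significance rate for
#'   same-distribution groups, n = 30) and recovery of a doubled group mean,
#'   over `n_datasets` simulated datasets.
#' @param n_datasets simulated datasets per condition.
#' @export
benchmark_bootstrap <- function(seed = 1, n_datasets = 200) {
  null_sig <- logical(n_datasets)
  shift_sig <- logical(n_datasets)
  est <- numeric(n_datasets)
  for (i in seq_len(n_datasets)) {
    d <- with_seed(seed * 10000 + i, {
      list(a = stats::rnorm(30, 10, 1), b = stats::rnorm(30, 10, 1))
    })
    r0 <- bootstrap_contrast(d$a, d$b, bootstrap_config(seed = seed * 20000 + i))
    null_sig[i] <- r0$significant
    b2 <- with_seed(seed * 30000 + i, 2 * stats::rnorm(30, 10, 1))
    r2 <- bootstrap_contrast(d$a, b2, bootstrap_config(seed = seed * 40000 + i))
    shift_sig[i] <- r2$significant
    est[i] <- r2$point_estimate
  }
  list(null_significance_rate = mean(null_sig),
       shift_detection_rate = mean(shift_sig),
       shift_estimate = mean(est),
       n_datasets = n_datasets)
}

#' @describeIn benchmarks multitaper peak localization of a 20 Hz unit sine
#'   and the exactness of spectrum normalization.
#' @export
benchmark_multitaper <- function(seed = 1) {
  fs <- 1000
  t <- (seq_len(10 * fs) - 1) / fs
  p <- multitaper_psd(sin(2 * pi * 20 * t), fs_hz = fs)
  peak_hz <- p$freq_hz[which.max(p$power)]
  noise <- with_seed(seed, stats::rnorm(10 * fs))
  np <- normalize_psd(multitaper_psd(noise, fs_hz = fs))
  f <- np$freq_hz
  sup <- f >= 1 & f <= 90 & !(f >= 48 & f <= 52)
  list(sine_peak_hz = peak_hz,
       norm_mean_error = abs(mean(np$power[sup]) - 1))
}

#' @describeIn benchmarks recovery of injected beta bursts (8 dB, FWHM
#'   300 ms, 10/min over 600 s): count ratio and median-duration ratio
#'   against injected truth, and median peak-time error against the
#'   realized band-envelope maximum within each true event (the identifiable
#'   peak; background noise displaces the realized envelope peak from the
#'   injected center irrespective of the detector).
#' @export
benchmark_lfp_bursts <- function(seed = 1) {
  cfg <- lfp_synth_config(duration_s = 600,
                          burst_specs = list(burst_spec(13, 30,
                                                        rate_per_min = 10,
                                                        duration_ms_mean = 300,
                                                        amplitude_db = 8)),
                          seed = seed)
  sim <- gen_lfp(cfg)
  ev <- detect_osc_bursts(sim$trace, c(13, 30))
  fs <- sim$trace$fs_hz
  bp <- butter_filtfilt(sim$trace$samples, fs, low = 13, high = 30)
  env <- moving_average(Mod(hilbert_analytic(bp)), round(4 / 21.5 * fs))
  realized_peak <- vapply(seq_len(nrow(sim$truth)), function(i) {
    i0 <- max(1L, round(sim$truth$start_s[i] * fs))
    i1 <- min(length(env), round(sim$truth$end_s[i] * fs))
    (i0:i1)[which.max(env[i0:i1])] / fs
  }, numeric(1))
  peak_err <- vapply(realized_peak,
                     function(p) min(abs(ev$peak_s - p)), numeric(1))
  list(n_true = nrow(sim$truth), n_detected = nrow(ev),
       count_ratio = nrow(ev) / nrow(sim$truth),
       duration_ratio = stats::median(ev$duration_s) /
         stats::median(sim$truth$duration_s),
       median_peak_error_ms = stats::median(peak_err) * 1000)
}

#' @describeIn benchmarks narrow/wide unit classification accuracy across
#'   `n_seeds` generator seeds (30 + 30 units each), and whether the
#'   narrower cluster is always labeled the putative PV interneuron.
#' @param n_seeds number of independent waveform sets.
#' @export
benchmark_classification <- function(seed = 1, n_seeds = 20) {
  acc <- numeric(n_seeds)
  narrow_ok <- logical(n_seeds)
  for (s in seq_len(n_seeds)) {
    base <- seed * 1000 + s
    wn <- gen_unit_waveform("narrow", 30, noise_sd_uv = 8, seed = base)
    ww <- gen_unit_waveform("wide", 30, noise_sd_uv = 8, seed = base + 500)
    feats <- do.call(rbind, lapply(c(wn, ww), function(w) {
      as.data.frame(waveform_features(w))
    }))
    feats$rate_hz <- with_seed(base + 900, c(stats::rexp(30, 1 / 15) + 5,
                                             stats::rexp(30, 1 / 4) + 0.5))
    truth <- rep(c("putative_PV_IN", "putative_SPN"), each = 30)
    lab <- classify_units(feats, seed = base)
    acc[s] <- mean(lab == truth)
    narrow_ok[s] <- mean(feats$trough_to_peak_ms[lab == "putative_PV_IN"]) <
      mean(feats$trough_to_peak_ms[lab == "putative_SPN"])
  }
  list(mean_accuracy = mean(acc), min_accuracy = min(acc),
       narrow_always_pv = all(narrow_ok), n_seeds = n_seeds)
}

#' @describeIn benchmarks short-term-plasticity recovery: pulse-2 ratio
#'   error at 2% measurement noise and the exact first-pulse normalization.
#' @export
benchmark_stp <- function(seed = 1) {
  errs <- vapply(seq_len(5), function(i) {
    cfg <- stp_synth_config(release_prob = 0.5, tau_rec_s = 0.5, amp1_pa = 100,
                            noise_sd_pa = 2, seed = seed * 10 + i)
    sim <- gen_evoked_train(cfg)
    p <- stp_profile(sim$trace, sim$stim_times_s, "EPSC")
    true_ppr <- sim$true_amplitudes_pa[2] / sim$true_amplitudes_pa[1]
    c(abs(p$ppr - true_ppr) / true_ppr, p$normalized_amplitudes[1])
  }, numeric(2))
  list(max_ppr_rel_error = max(errs[1, ]),
       first_pulse_normalized = unique(errs[2, ]))
}
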