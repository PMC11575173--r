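test_that("baseline removal cancels constants and slow drift", {
  fs <- 5000
  const <- trace(rep(12.3, fs * 3), fs)
  expect_equal(remove_baseline(const)$samples, rep(0, fs * 3))
  zero <- trace(numeric(fs * 3), fs)
  expect_equal(remove_baseline(zero)$samples, rep(0, fs * 3))
  # slow sine + one fast event: residual baseline stays small outside event
  t <- (seq_len(fs * 12) - 1) / fs
  x <- 20 * sin(2 * pi * t / 10)
  ev <- make_event_trace(6, 50, duration_s = 12, fs = fs)
  tr <- trace(x + ev$samples, fs)
  out <- remove_baseline(tr)$samples
  outside <- abs(t - 6) > 0.2 & t > 0.5 & t < 11.5
  expect_lt(max(abs(out[outside] - ev$samples[outside])), 2)
})

test_that("baseline removal agrees with a brute-force running median", {
  fs <- 5000
  set.seed(3)
  x <- cumsum(rnorm(fs * 2)) / 50
  tr <- trace(x, fs)
  out <- remove_baseline(tr, window_s = 0.2)$samples
  k <- round(0.2 * fs) + 1  # forced odd inside
  i <- 3000
  manual <- x[i] - median(x[(i - (k - 1) / 2):(i + (k - 1) / 2)])
  expect_equal(out[i], manual, tolerance = 1e-12)
  expect_error(remove_baseline(trace(rnorm(100), fs)), "longer than trace")
})

test_that("slope method finds fast-rising inward events and nothing else", {
  fs <- 10000
  rising <- trace(seq(0, 100, length.out = fs), fs)
  expect_length(detect_slope(rising), 0)
  one <- make_event_trace(1, 60, duration_s = 2)
  cand <- detect_slope(one)
  expect_length(cand, 1)
  expect_lt(abs(cand - 1), 0.001)
  two <- make_event_trace(c(0.8, 0.85), c(60, 60), duration_s = 2)
  expect_length(detect_slope(two), 2)
})

test_that("high-band amplitude method detects events and stays quiet on zeros", {
  one <- make_event_trace(1, 60, duration_s = 2)
  expect_length(detect_highband(one), 1)
  zero <- trace(numeric(20000), 10000)
  expect_length(detect_highband(zero), 0)
  # Gaussian noise: few crossings at 4.5 robust SD
  set.seed(8)
  noise <- trace(rnorm(10000 * 30, 0, 5), 10000)
  n_fp <- length(detect_highband(remove_baseline(noise)))
  expect_lt(n_fp / 30, 0.5)
})

test_that("multi-band method captures slow-rise events the slope method misses", {
  slow <- make_event_trace(1, 40, duration_s = 2, tau_rise = 2, tau_decay = 12)
  expect_gte(length(detect_multiband(slow)), 1)
  expect_length(detect_multiband(trace(numeric(20000), 10000)), 0)
  # candidates in several bands merge to one
  cand <- detect_multiband(make_event_trace(1, 80, duration_s = 2))
  expect_length(cand, 1)
})

test_that("candidate combination is a deduplicated union with provenance", {
  cfg <- detector_config(merge_tol_ms = 2)
  comb <- combine_candidates(list(slope = 1.0000, highband = 1.0005,
                                  multiband = 1.0010), cfg)
  expect_equal(nrow(comb), 1)
  expect_equal(comb$onset_s, 1)
  expect_equal(comb$detected_by, "highband,multiband,slope")
  comb2 <- combine_candidates(list(slope = c(1, 3), highband = 2), cfg)
  expect_equal(comb2$onset_s, c(1, 2, 3))
  comb3 <- combine_candidates(list(slope = 1.0, highband = 1.0005), cfg)
  expect_equal(nrow(comb3), 1)
  expect_equal(comb3$onset_s, 1.0)
})

test_that("event measurement recovers amplitude and decay kinetics", {
  tr <- make_event_trace(1, 50, duration_s = 3)
  ev <- measure_events(tr, 1)
  expect_equal(ev$amplitude_pa, 50, tolerance = 0.02 * 50)
  expect_equal(ev$decay_tau_ms, 5, tolerance = 0.5)
  expect_gt(ev$rise_20_80_ms, 0.1)
  expect_error(measure_events(tr, 5), "outside trace")
})

test_that("an event truncated at the trace end keeps amplitude, loses decay", {
  fs <- 10000
  tr <- make_event_trace(1.998, 50, duration_s = 2, fs = fs)
  ev <- measure_events(tr, 1.998)
  expect_gt(ev$amplitude_pa, 30)
  expect_true(is.na(ev$decay_tau_ms))
})

test_that("event frequency is count over duration", {
  expect_equal(event_frequency(data.frame()[0, ], 100), 0)
  expect_equal(event_frequency(200, 100), 2)
  expect_error(event_frequency(1, 0), "analyzed_duration_s")
})

test_that("recording inclusion applies the holding-current and Rs thresholds", {
  r1 <- include_recording(-250, 20)
  expect_false(r1$include); expect_match(r1$reason, "holding current")
  r2 <- include_recording(-100, 26)
  expect_false(r2$include); expect_match(r2$reason, "series resistance")
  r3 <- include_recording(-100, 20)
  expect_true(r3$include); expect_equal(r3$reason, "")
})

test_that("detection is offset-invariant and polarity-symmetric", {
  cfg <- psc_synth_config(duration_s = 20, event_rate_hz = 1, amp_mean_pa = 30,
                          noise_sd_pa = 4, seed = 31)
  sim <- gen_psc_trace(cfg)
  ev0 <- suppressWarnings(detect_psc(sim$trace, "sEPSC"))
  shifted <- trace(sim$trace$samples + 137, sim$trace$fs_hz)
  ev1 <- suppressWarnings(detect_psc(shifted, "sEPSC"))
  expect_equal(ev1$onset_s, ev0$onset_s)
  flipped <- trace(-sim$trace$samples, sim$trace$fs_hz)
  cfg_noslope <- detector_config(use_slope_method = FALSE)
  evi <- suppressWarnings(detect_psc(flipped, "sIPSC", cfg_noslope))
  eve <- suppressWarnings(detect_psc(sim$trace, "sEPSC", cfg_noslope))
  expect_equal(evi$onset_s, eve$onset_s)
  expect_equal(evi$amplitude_pa, eve$amplitude_pa)
})

test_that("detection is deterministic for identical traces", {
  cfg <- psc_synth_config(duration_s = 10, seed = 17)
  tr <- gen_psc_trace(cfg)$trace
  e1 <- suppressWarnings(detect_psc(tr, "sEPSC"))
  e2 <- suppressWarnings(detect_psc(tr, "sEPSC"))
  expect_identical(e1, e2)
})

test_that("detector meets recall/precision targets on a study-condition trace", {
  cfg <- psc_synth_config(duration_s = 60, event_rate_hz = 2, amp_mean_pa = 25,
                          amp_cv = 0.4, noise_sd_pa = 5, drift_amp_pa = 10,
                          seed = 42)
  sim <- gen_psc_trace(cfg)
  ev <- suppressWarnings(detect_psc(sim$trace, "sEPSC"))
  m <- match_events(ev$onset_s, sim$truth$onset_s, tol_ms = 2)
  expect_gte(m$recall, 0.90)
  expect_gte(m$precision, 0.90)
})

test_that("pure noise yields almost no false events", {
  sim <- gen_psc_trace(psc_synth_config(duration_s = 60, event_rate_hz = 0,
                                        noise_sd_pa = 5, seed = 9))
  ev <- suppressWarnings(detect_psc(sim$trace, "sEPSC"))
  expect_lte(nrow(ev) / 60, 0.2)
})
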