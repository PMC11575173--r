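test_that("LFP preprocessing decimates and band-limits correctly", {
  fs <- 30000
  t <- (seq_len(fs * 4) - 1) / fs
  raw <- trace(5 * sin(2 * pi * 20 * t) + 3, fs, units = "uV")
  lfp <- preprocess_lfp(raw)
  expect_equal(lfp$fs_hz, 1000)
  mid <- lfp$samples[1000:3000]
  expect_equal(max(mid), 5, tolerance = 0.05)       # amplitude preserved
  expect_lt(abs(mean(lfp$samples)), 0.1)            # DC removed
  # 600 Hz tone attenuated by the anti-alias stage
  raw600 <- trace(10 * sin(2 * pi * 600 * t), fs, units = "uV")
  lfp600 <- preprocess_lfp(raw600)
  atten_db <- 20 * log10(sd(lfp600$samples[1000:3000]) / (10 / sqrt(2)))
  expect_lt(atten_db, -20)
  expect_error(preprocess_lfp(trace(rnorm(500), 500)), "sampling rate")
})

test_that("segmentation drops artifact windows and trailing remainders", {
  fs <- 1000
  tr <- trace(rnorm(fs * 95), fs)
  segs <- segment_lfp(tr)
  expect_length(segs, 9)
  mask <- rep(FALSE, fs * 95)
  mask[15 * fs] <- TRUE
  segs2 <- segment_lfp(tr, mask)
  expect_length(segs2, 8)
  expect_equal(attr(segs2, "n_dropped"), 1)
  expect_warning(segment_lfp(tr, rep(TRUE, fs * 95)), "masked")
})

test_that("slepian tapers match a dense-eigenproblem oracle", {
  n <- 64
  w <- 3 / n
  i <- seq_len(n) - 1
  Td <- diag(((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w))
  e <- seq_len(n - 1) * (n - seq_len(n - 1)) / 2
  for (j in seq_len(n - 1)) {
    Td[j, j + 1] <- e[j]; Td[j + 1, j] <- e[j]
  }
  eg <- eigen(Td, symmetric = TRUE)
  tap <- dpss_tapers(n, 3, 5)
  for (k in 1:5) {
    ref <- eg$vectors[, k]
    err <- min(max(abs(tap[, k] - ref)), max(abs(tap[, k] + ref)))
    expect_lt(err, 1e-8)
  }
  expect_equal(crossprod(tap), diag(5), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("multitaper resolves sinusoids at the stated resolution", {
  fs <- 1000
  t <- (seq_len(10 * fs) - 1) / fs
  p <- multitaper_psd(sin(2 * pi * 20 * t), fs_hz = fs)
  expect_equal(p$freq_hz[which.max(p$power)], 20, tolerance = 0.1)
  # two tones 1 Hz apart resolved with TW = 3 over 10 s (half-bandwidth 0.3 Hz)
  x2 <- sin(2 * pi * 20 * t) + sin(2 * pi * 21 * t)
  p2 <- multitaper_psd(x2, fs_hz = fs)
  sel <- p2$freq_hz >= 19 & p2$freq_hz <= 22
  f_sel <- p2$freq_hz[sel]; pow_sel <- p2$power[sel]
  expect_gt(pow_sel[f_sel == 20], pow_sel[f_sel == 20.5])
  expect_gt(pow_sel[f_sel == 21], pow_sel[f_sel == 20.5])
})

test_that("averaging across segments shrinks spectral variance", {
  set.seed(12)
  fs <- 1000
  segs1 <- list(rnorm(2 * fs))
  segs8 <- lapply(1:8, function(i) rnorm(2 * fs))
  p1 <- multitaper_psd(segs1, fs_hz = fs)
  p8 <- multitaper_psd(segs8, fs_hz = fs)
  sel <- p1$freq_hz > 10 & p1$freq_hz < 400
  expect_lt(sd(p8$power[sel]), sd(p1$power[sel]))
})

test_that("PSD normalization yields unit mean over its support", {
  set.seed(13)
  fs <- 1000
  p <- multitaper_psd(rnorm(10 * fs), fs_hz = fs)
  np <- normalize_psd(p)
  f <- np$freq_hz
  sup <- f >= 1 & f <= 90 & !(f >= 48 & f <= 52)
  expect_lt(abs(mean(np$power[sup]) - 1), 1e-9)
  flat <- structure(list(freq_hz = seq(0, 100, by = 0.1),
                         power = rep(2.5, 1001), fs_hz = 1000), class = "psd")
  nf <- normalize_psd(flat)
  expect_equal(unique(nf$power), 1)
  zero <- structure(list(freq_hz = seq(0, 100, by = 0.1),
                         power = numeric(1001), fs_hz = 1000), class = "psd")
  expect_error(normalize_psd(zero), "degenerate")
})

test_that("band power averages the normalized spectrum over the band", {
  flat <- structure(list(freq_hz = seq(0, 100, by = 0.1),
                         power = rep(1, 1001), fs_hz = 1000), class = "psd")
  for (b in osc_bands()) expect_equal(band_power(flat, b[1], b[2]), 1)
  expect_error(band_power(flat, 90, 200), "outside")
  peaked <- flat
  peaked$power[peaked$freq_hz >= 13 & peaked$freq_hz < 30] <- 10
  expect_gt(band_power(peaked, 13, 30), band_power(peaked, 60, 90))
})

test_that("burst detector applies the dual dB thresholds", {
  # a strong injected burst is detected at its location
  cfg <- lfp_synth_config(duration_s = 60, background_exponent = 1.5,
                          background_rms_uv = 30,
                          burst_specs = list(burst_spec(13, 30, rate_per_min = 1,
                                                        duration_ms_mean = 300,
                                                        amplitude_db = 14)),
                          seed = 5)
  sim <- gen_lfp(cfg)
  expect_equal(nrow(sim$truth), 1)
  ev <- detect_osc_bursts(sim$trace, c(13, 30))
  near <- abs(ev$peak_s - sim$truth$peak_s) < 0.05
  expect_equal(sum(near), 1)
  expect_gt(ev$peak_db_over_background[near], 6)
  expect_true(all(ev$start_s < ev$peak_s & ev$peak_s < ev$end_s))
  expect_equal(ev$duration_s, ev$end_s - ev$start_s)
  # the same burst injected below the peak threshold is not reported there
  cfg3 <- cfg
  cfg3$burst_specs[[1]]$amplitude_db <- 3
  sim3 <- gen_lfp(cfg3)
  ev3 <- detect_osc_bursts(sim3$trace, c(13, 30))
  expect_false(any(abs(ev3$peak_s - sim3$truth$peak_s) < 0.1))
  expect_error(detect_osc_bursts(sim$trace, c(400, 600)), "Nyquist")
})

test_that("raising the peak threshold never increases the event count", {
  cfg <- lfp_synth_config(duration_s = 300,
                          burst_specs = list(burst_spec(13, 30, rate_per_min = 8,
                                                        amplitude_db = 8)),
                          seed = 32)
  sim <- gen_lfp(cfg)
  n_prev <- Inf
  for (pk in c(4, 6, 8, 10)) {
    n <- nrow(detect_osc_bursts(sim$trace, c(13, 30),
                                burst_detect_config(dbpeak = pk)))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("burst statistics summarize rate and duration", {
  ev <- data.frame(start_s = c(1, 5), peak_s = c(1.1, 5.1), end_s = c(1.3, 5.4),
                   duration_s = c(0.3, 0.4), peak_freq_hz = c(20, 22),
                   peak_db_over_background = c(7, 9))
  st <- burst_statistics(ev, 600)
  expect_equal(st$rate_per_min, 0.2)
  expect_equal(st$mean_duration_s, 0.35)
  expect_true(st$amplitude_impedance_dependent)
  st0 <- burst_statistics(ev[0, ], 600)
  expect_equal(st0$rate_per_min, 0)
  expect_true(is.na(st0$mean_duration_s))
  expect_error(burst_statistics(ev, 0), "analyzed_duration_s")
})

test_that("event-aligned spectrograms localize injected bursts", {
  cfg <- lfp_synth_config(duration_s = 200, background_exponent = 1,
                          background_rms_uv = 20,
                          burst_specs = list(burst_spec(18, 22, rate_per_min = 6,
                                                        duration_ms_mean = 250,
                                                        amplitude_db = 12)),
                          seed = 33)
  sim <- gen_lfp(cfg)
  sp <- event_aligned_spectrogram(sim$trace, sim$truth$peak_s,
                                  freq_range = c(5, 45), window_s = 0.5,
                                  n_freq = 41)
  peak_idx <- which(sp$power == max(sp$power), arr.ind = TRUE)
  expect_lt(abs(sp$freq_hz[peak_idx[1]] - 20), 2)
  expect_lt(abs(sp$time_s[peak_idx[2]]), 0.05)
  expect_true(all(apply(sp$power, 1, max) <= 1 + 1e-12))
  # single event: average equals that event's row-normalized spectrogram
  sp1 <- event_aligned_spectrogram(sim$trace, sim$truth$peak_s[1],
                                   freq_range = c(10, 30), window_s = 0.3,
                                   n_freq = 11)
  expect_equal(unname(apply(sp1$power, 1, max)), rep(1, 11), tolerance = 1e-9)
  expect_error(event_aligned_spectrogram(sim$trace, numeric(0), c(5, 45)),
               "no events")
})

test_that("band-power time courses are flat at baseline and track amplitude", {
  fs <- 1000
  t <- (seq_len(300 * fs) - 1) / fs
  amp <- ifelse(t < 150, 1, 2)   # gamma amplitude doubles at t = 150
  set.seed(34)
  x <- amp * sin(2 * pi * 45 * t) + 0.2 * rnorm(length(t))
  tc <- band_power_timecourse(trace(x, fs), bands = list(low_gamma = c(30, 60)),
                              window_s = 10, step_s = 10,
                              baseline_interval = c(0, 100))
  pre <- tc$low_gamma[tc$time_s < 140]
  post <- tc$low_gamma[tc$time_s > 160]
  expect_equal(mean(pre), 1, tolerance = 0.05)
  expect_equal(mean(post), 4, tolerance = 0.3)   # amplitude^2 scaling
  expect_error(band_power_timecourse(trace(x, fs),
                                     baseline_interval = c(500, 600)),
               "baseline")
})

test_that("artifact flagging marks extreme excursions only", {
  set.seed(35)
  x <- rnorm(10000)
  x[5000:5010] <- 100
  tr <- trace(x, 1000)
  m <- flag_artifacts(tr)
  expect_true(all(m[5000:5010]))
  expect_lt(mean(m[-(4990:5020)]), 0.001)
})
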