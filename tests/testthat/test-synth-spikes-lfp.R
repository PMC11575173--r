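test_that("spike generator respects duration and rate", {
  expect_length(gen_spike_train(spike_synth_config(duration_s = 0, seed = 1)), 0)
  st <- gen_spike_train(spike_synth_config(duration_s = 1000, rate_hz = 10,
                                           refractory_ms = 0, seed = 2))
  expect_lt(abs(length(st) - 10000), 3 * sqrt(10000))
  expect_false(is.unsorted(st))
})

test_that("refractory thinning enforces the minimum ISI", {
  st <- gen_spike_train(spike_synth_config(duration_s = 100, rate_hz = 50,
                                           refractory_ms = 2, seed = 3))
  expect_true(all(diff(st) >= 0.002 - 1e-12))
})

test_that("bursty trains have modal ISI near the intra-burst interval", {
  st <- gen_spike_train(spike_synth_config(duration_s = 300, mode = "bursty",
                                           burst_rate_hz = 1,
                                           spikes_per_burst_mean = 5,
                                           intra_burst_isi_ms = 5, seed = 4))
  isi <- diff(st) * 1000
  h <- hist(isi[isi < 50], breaks = seq(0, 50, by = 1), plot = FALSE)
  modal <- h$mids[which.max(h$counts)]
  expect_gt(modal, 2)
  expect_lt(modal, 10)
})

test_that("unit waveform classes occupy their trough-to-peak ranges", {
  expect_length(gen_unit_waveform("narrow", 0), 0)
  wn <- gen_unit_waveform("narrow", 5, noise_sd_uv = 0, seed = 1)
  ww <- gen_unit_waveform("wide", 5, noise_sd_uv = 0, seed = 1)
  t2p_n <- vapply(wn, function(w) waveform_features(w)$trough_to_peak_ms, 0)
  t2p_w <- vapply(ww, function(w) waveform_features(w)$trough_to_peak_ms, 0)
  expect_true(all(t2p_n >= 0.2 & t2p_n <= 0.4))
  expect_true(all(t2p_w >= 0.6 & t2p_w <= 1.0))
  expect_error(gen_unit_waveform("medium", 3), "arg")
})

test_that("narrow and wide waveform features separate almost perfectly", {
  wn <- gen_unit_waveform("narrow", 100, noise_sd_uv = 10, seed = 5)
  ww <- gen_unit_waveform("wide", 100, noise_sd_uv = 10, seed = 6)
  t2p <- vapply(c(wn, ww), function(w) waveform_features(w)$trough_to_peak_ms, 0)
  km <- kmeans(t2p, centers = 2, nstart = 10)
  truth <- rep(1:2, each = 100)
  agree <- max(mean(km$cluster == truth), mean(km$cluster == 3 - truth))
  expect_gte(agree, 0.99)
})

test_that("flat-spectrum LFP background is white", {
  cfg <- lfp_synth_config(duration_s = 60, background_exponent = 0, seed = 7)
  sim <- gen_lfp(cfg)
  p <- multitaper_psd(segment_lfp(sim$trace))
  sel_lo <- p$freq_hz >= 5 & p$freq_hz < 100
  sel_hi <- p$freq_hz >= 200 & p$freq_hz < 400
  expect_lt(abs(log(mean(p$power[sel_lo]) / mean(p$power[sel_hi]))), 0.2)
})

test_that("power-law background follows the configured exponent", {
  cfg <- lfp_synth_config(duration_s = 120, background_exponent = 2, seed = 8)
  sim <- gen_lfp(cfg)
  p <- multitaper_psd(segment_lfp(sim$trace))
  sel <- p$freq_hz >= 5 & p$freq_hz <= 100
  fit <- lm(log(p$power[sel]) ~ log(p$freq_hz[sel]))
  expect_equal(unname(coef(fit)[2]), -2, tolerance = 0.15)
})

test_that("injected burst envelope peaks at the ground-truth time", {
  cfg <- lfp_synth_config(duration_s = 60, background_rms_uv = 0,
                          burst_specs = list(burst_spec(18, 22, rate_per_min = 1,
                                                        duration_ms_mean = 300,
                                                        amplitude_db = 20)),
                          seed = 21)
  sim <- gen_lfp(cfg)
  expect_gt(nrow(sim$truth), 0)
  bp <- striatools:::butter_filtfilt(sim$trace$samples, 1000, low = 15, high = 25)
  env <- Mod(striatools:::hilbert_analytic(bp))
  for (i in seq_len(nrow(sim$truth))) {
    idx <- round((sim$truth$peak_s[i] + c(-0.5, 0.5)) * 1000)
    loc <- (idx[1]:idx[2])[which.max(env[idx[1]:idx[2]])] / 1000
    expect_lt(abs(loc - sim$truth$peak_s[i]), 0.010)
  }
})

test_that("burst counts follow the configured Poisson rate", {
  n_b <- vapply(1:40, function(s) {
    cfg <- lfp_synth_config(duration_s = 600, background_rms_uv = 0,
                            burst_specs = list(burst_spec(13, 30,
                                                          rate_per_min = 10)),
                            seed = s)
    nrow(gen_lfp(cfg)$truth)
  }, numeric(1))
  expect_lt(abs(mean(n_b) - 100), 3 * sqrt(100 / 40))
})

test_that("bands beyond Nyquist are rejected", {
  expect_error(lfp_synth_config(fs_hz = 200,
                                burst_specs = list(burst_spec(60, 120))),
               "Nyquist")
})
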