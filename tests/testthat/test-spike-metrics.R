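test_that("quality gate applies all four thresholds", {
  qm <- function(a, v, nc, s) list(amplitude_uv = a, isi_violation_pct = v,
                                   noise_cutoff = nc, snr = s)
  expect_true(quality_pass(qm(60, 0.1, 0.1, 3.0))$pass)
  r <- quality_pass(qm(45, 0.1, 0.1, 3.0))
  expect_false(r$pass); expect_equal(r$failed, "amplitude")
  r2 <- quality_pass(qm(60, 0.6, 0.1, 3.0))
  expect_false(r2$pass); expect_equal(r2$failed, "isi_violation")
  r3 <- quality_pass(qm(60, 0.1, 0.6, 2.0))
  expect_setequal(r3$failed, c("noise_cutoff", "snr"))
})

test_that("quality metrics reflect ISI violations and waveform amplitude", {
  u_reg <- spike_unit(seq(0.1, 10, by = 0.1), recording_duration_s = 10)
  expect_equal(compute_quality(u_reg)$isi_violation_pct, 0)
  # every spike doubled 1 ms later: about half the ISIs violate
  t_base <- seq(0.1, 10, by = 0.1)
  t_dbl <- sort(c(t_base, t_base + 0.001))
  u_dbl <- spike_unit(t_dbl, recording_duration_s = 10.1)
  expect_equal(compute_quality(u_dbl)$isi_violation_pct, 50, tolerance = 2)
  u_flat <- spike_unit(c(1, 2), mean_waveform_uv = numeric(90),
                       recording_duration_s = 10)
  q <- compute_quality(u_flat)
  expect_equal(q$amplitude_uv, 0)
  expect_false(quality_pass(q)$pass)
})

test_that("autocorrelogram matches brute-force pair counting", {
  # simple case: two spikes 5 ms apart -> one count in the (4,5] bin
  acg <- autocorrelogram(c(0.100, 0.105))
  expect_equal(sum(acg$counts), 1)
  expect_equal(acg$counts[5], 1)
  expect_equal(sum(autocorrelogram(numeric(0))$counts), 0)
  expect_equal(sum(autocorrelogram(0.5)$counts), 0)
  # random train vs O(n^2) oracle
  set.seed(4)
  st <- sort(runif(400, 0, 10))
  acg2 <- autocorrelogram(st, bin_ms = 1, max_lag_ms = 50)
  brute <- integer(50)
  for (i in seq_along(st)) for (j in seq_along(st)) {
    if (j > i) {
      lag <- (st[j] - st[i]) * 1000
      if (lag > 0 && lag <= 50) {
        b <- ceiling(lag)
        brute[b] <- brute[b] + 1L
      }
    }
  }
  expect_equal(acg2$counts, brute)
})

test_that("burst index hits its analytic extremes", {
  # all ISIs ~5 ms: head only -> +1
  bursty <- seq(0, 1, by = 0.005)
  expect_equal(burst_index(autocorrelogram(bursty, max_lag_ms = 12))$index, 1)
  # regular 40 ms train within a 50 ms window: tail only -> -1
  regular <- seq(0, 4, by = 0.040)
  expect_equal(burst_index(autocorrelogram(regular))$index, -1)
  # empty head and tail -> undefined
  sparse <- c(0, 1, 2)
  expect_true(is.na(burst_index(autocorrelogram(sparse))$index))
})

test_that("burst index of a Poisson train approaches the flat-ACG value", {
  st <- gen_spike_train(spike_synth_config(duration_s = 2500, rate_hz = 20,
                                           refractory_ms = 0, seed = 44))
  bi <- burst_index(autocorrelogram(st))
  expect_equal(bi$index, -7 / 23, tolerance = 0.03)
})

test_that("burst index is translation-invariant and bounded", {
  set.seed(5)
  st <- sort(runif(500, 0, 20))
  b1 <- burst_index(autocorrelogram(st))
  b2 <- burst_index(autocorrelogram(st + 123.4))
  expect_equal(b1$index, b2$index)
  expect_gte(b1$index, -1); expect_lte(b1$index, 1)
})

test_that("mean rate is spikes over duration", {
  u <- spike_unit(seq(0.05, 99.95, length.out = 1000), recording_duration_s = 100)
  expect_equal(mean_rate(u), 10)
  expect_equal(mean_rate(spike_unit(numeric(0), recording_duration_s = 10)), 0)
  expect_error(mean_rate(spike_unit(numeric(0), recording_duration_s = 0)),
               "duration")
})

test_that("waveform features require a biphasic shape", {
  w <- gen_unit_waveform("narrow", 1, noise_sd_uv = 0, seed = 1)[[1]]
  f <- waveform_features(w)
  expect_true(all(vapply(f, is.finite, TRUE)))
  expect_error(waveform_features(seq(1, 10)), "biphasic")
})

test_that("unit classification separates generator classes and is stable", {
  mk_feats <- function(seed) {
    wn <- gen_unit_waveform("narrow", 15, noise_sd_uv = 8, seed = seed)
    ww <- gen_unit_waveform("wide", 15, noise_sd_uv = 8, seed = seed + 500)
    f <- do.call(rbind, lapply(c(wn, ww),
                               function(w) as.data.frame(waveform_features(w))))
    f$rate_hz <- striatools:::with_seed(seed, c(rexp(15, 1 / 15) + 5,
                                                rexp(15, 1 / 4) + 0.5))
    f
  }
  feats <- mk_feats(7)
  truth <- rep(c("putative_PV_IN", "putative_SPN"), each = 15)
  lab <- classify_units(feats, seed = 1)
  expect_gte(mean(lab == truth), 0.95)
  # invariant to row permutation
  perm <- striatools:::with_seed(2, sample(nrow(feats)))
  lab_p <- classify_units(feats[perm, ], seed = 1)
  expect_gte(mean(lab_p == truth[perm]), 0.95)
  # degenerate inputs refused
  same <- feats[rep(1, 6), ]
  expect_error(classify_units(same, seed = 1), "identical")
  expect_error(classify_units(feats[1:3, ], seed = 1), "insufficient")
})
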