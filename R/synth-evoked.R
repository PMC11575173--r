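#' Configuration for synthetic evoked 20 Hz trains
#'
#' A deterministic resource-utilization (Tsodyks-Markram-style) recurrence
#' drives the per-pulse amplitudes: each pulse releases a fraction `u` of the
#' available resource `R`, the resource recovers exponentially with
#' `tau_rec_s`, and utilization can facilitate by `facil_incr` decaying with
#' `tau_facil_s`. Measurement noise is additive on the trace.
#'
#' @param n_pulses number of pulses (default 8).
#' @param rate_hz stimulation rate (default 20 Hz, 50 ms spacing).
#' @param release_prob initial release probability / utilization, in (0, 1].
#' @param tau_rec_s resource recovery time constant (s).
#' @param facil_incr facilitation increment per pulse (0 = none).
#' @param tau_facil_s facilitation decay time constant (s).
#' @param amp1_pa first-pulse amplitude (pA, magnitude).
#' @param tau_rise_ms,tau_decay_ms PSC kernel kinetics.
#' @param fs_hz trace sampling rate.
#' @param noise_sd_pa additive noise SD on the trace.
#' @param polarity `"inward"` or `"outward"`.
#' @param seed RNG seed.
#' @return an `stp_synth_config` list.
#' @export
stp_synth_config <- function(n_pulses = 8, rate_hz = 20, release_prob = 0.5,
                             tau_rec_s = 0.5, facil_incr = 0, tau_facil_s = 0.1,
                             amp1_pa = 100, tau_rise_ms = 0.5, tau_decay_ms = 5,
                             fs_hz = 10000, noise_sd_pa = 0,
                             polarity = c("inward", "outward"), seed = NULL) {
  polarity <- match.arg(polarity)
  check_that(n_pulses >= 2, "n_pulses must be >= 2, got %d", n_pulses)
  check_that(release_prob > 0 && release_prob <= 1,
             "release_prob must be in (0, 1], got %g", release_prob)
  check_that(rate_hz > 0, "rate_hz must be > 0, got %g", rate_hz)
  check_that(amp1_pa > 0, "amp1_pa must be > 0, got %g", amp1_pa)
  structure(as.list(environment()), class = "stp_synth_config")
}

#' True per-pulse amplitudes of the resource-depletion model
#'
#' Iterates the recurrence without noise: at pulse k, `A_k = amp1 * R_k *
#' u_k / (R_1 u_1)`; between pulses `R` recovers toward 1 with `tau_rec_s`
#' and `u` decays toward `release_prob` with `tau_facil_s` after being
#' incremented by `facil_incr * (1 - u)` at each pulse.
#'
#' @param cfg an [stp_synth_config()].
#' @return numeric vector of `n_pulses` true amplitudes (pA).
#' @export
stp_true_amplitudes <- function(cfg) {
  dt <- 1 / cfg$rate_hz
  R <- 1
  u <- cfg$release_prob
  amps <- numeric(cfg$n_pulses)
  for (k in seq_len(cfg$n_pulses)) {
    amps[k] <- R * u
    R_after <- R * (1 - u)
    R <- 1 - (1 - R_after) * exp(-dt / cfg$tau_rec_s)
    u_after <- u + cfg$facil_incr * (1 - u)
    u <- cfg$release_prob + (u_after - cfg$release_prob) * exp(-dt / cfg$tau_facil_s)
  }
  cfg$amp1_pa * amps / amps[1]
}

#' Generate a synthetic evoked train trace
#'
#' @param cfg an [stp_synth_config()].
#' @param pre_s quiet baseline before the first stimulus (s).
#' @param post_s tail after the last stimulus (s).
#' @return list with `trace`, `stim_times_s` and `true_amplitudes_pa`.
#' @export
gen_evoked_train <- function(cfg, pre_s = 0.1, post_s = 0.2) {
  check_that(inherits(cfg, "stp_synth_config"), "cfg must come from stp_synth_config()")
  amps <- stp_true_amplitudes(cfg)
  dt <- 1 / cfg$rate_hz
  stim <- pre_s + (seq_len(cfg$n_pulses) - 1) * dt
  dur <- pre_s + (cfg$n_pulses - 1) * dt + post_s
  n <- round(dur * cfg$fs_hz)
  with_seed(cfg$seed, {
    x <- if (cfg$noise_sd_pa > 0) stats::rnorm(n, 0, cfg$noise_sd_pa) else numeric(n)
    sign_ <- if (cfg$polarity == "inward") -1 else 1
    klen <- min(n, ceiling(8 * cfg$tau_decay_ms / 1000 * cfg$fs_hz))
    kern <- psc_kernel((seq_len(klen) - 1) / cfg$fs_hz, cfg$tau_rise_ms, cfg$tau_decay_ms)
    for (k in seq_len(cfg$n_pulses)) {
      i0 <- floor(stim[k] * cfg$fs_hz) + 1L
      idx <- i0:min(n, i0 + klen - 1L)
      x[idx] <- x[idx] + sign_ * amps[k] * kern[seq_along(idx)]
    }
    list(trace = trace(x, cfg$fs_hz, units = "pA",
                       meta = list(polarity = cfg$polarity)),
         stim_times_s = stim, true_amplitudes_pa = amps)
  })
}
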