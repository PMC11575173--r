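#' Biexponential postsynaptic-current kernel
#'
#' Difference of exponentials `exp(-t/tau_decay) - exp(-t/tau_rise)`,
#' peak-normalized to 1 so that the scaling coefficient is the event's peak
#' amplitude.
#'
#' @param t_s time from onset in seconds (>= 0).
#' @param tau_rise_ms,tau_decay_ms kinetics in ms; rise must be faster.
#' @return kernel values, peak value 1.
#' @export
psc_kernel <- function(t_s, tau_rise_ms, tau_decay_ms) {
  check_that(tau_rise_ms > 0 && tau_decay_ms > tau_rise_ms,
             "need 0 < tau_rise_ms (%g) < tau_decay_ms (%g)", tau_rise_ms, tau_decay_ms)
  tr <- tau_rise_ms / 1000
  td <- tau_decay_ms / 1000
  # analytic peak time and value of the difference of exponentials
  tpk <- tr * td / (td - tr) * log(td / tr)
  pk <- exp(-tpk / td) - exp(-tpk / tr)
  out <- (exp(-t_s / td) - exp(-t_s / tr)) / pk
  out[t_s < 0] <- 0
  out
}

#' Configuration for synthetic spontaneous PSC traces
#'
#' Defaults emulate sEPSC recordings: inward (negative) events at a few Hz
#' on a noisy, slowly drifting baseline.
#'
#' @param duration_s trace length in seconds.
#' @param fs_hz sampling rate (>= 5000 Hz).
#' @param event_rate_hz mean Poisson event rate.
#' @param amp_mean_pa mean peak amplitude (pA, magnitude).
#' @param amp_cv coefficient of variation of the lognormal amplitudes.
#' @param tau_rise_ms,tau_decay_ms biexponential kinetics.
#' @param polarity `"inward"` (negative, EPSC at -70 mV) or `"outward"`
#'   (positive, IPSC at 0 mV).
#' @param noise_sd_pa white-noise SD.
#' @param drift_amp_pa,drift_period_s sinusoidal baseline drift; a small
#'   random-walk component (`drift_walk_sd_pa`, per-sample SD) can be added.
#' @param drift_walk_sd_pa per-sample SD of an optional random-walk drift.
#' @param seed integer RNG seed.
#' @return a `psc_synth_config` list.
#' @export
psc_synth_config <- function(duration_s = 300, fs_hz = 10000,
                             event_rate_hz = 2, amp_mean_pa = 25, amp_cv = 0.4,
                             tau_rise_ms = 0.5, tau_decay_ms = 5,
                             polarity = c("inward", "outward"),
                             noise_sd_pa = 4, drift_amp_pa = 10,
                             drift_period_s = 30, drift_walk_sd_pa = 0,
                             seed = NULL) {
  polarity <- match.arg(polarity)
  check_that(duration_s > 0, "duration_s must be > 0, got %g", duration_s)
  check_that(fs_hz >= 5000, "fs_hz must be >= 5000, got %g", fs_hz)
  check_that(tau_rise_ms < tau_decay_ms,
             "tau_rise_ms (%g) must be < tau_decay_ms (%g)", tau_rise_ms, tau_decay_ms)
  check_that(amp_mean_pa > 0, "amp_mean_pa must be > 0, got %g", amp_mean_pa)
  check_that(event_rate_hz >= 0, "event_rate_hz must be >= 0, got %g", event_rate_hz)
  check_that(noise_sd_pa >= 0, "noise_sd_pa must be >= 0, got %g", noise_sd_pa)
  structure(as.list(environment()), class = "psc_synth_config")
}

#' Generate a synthetic spontaneous-PSC trace with ground truth
#'
#' Baseline drift plus Gaussian noise plus a Poisson train of peak-normalized
#' biexponential events with lognormal amplitudes. The returned ground truth
#' lists every injected event once; the same config and seed reproduce the
#' trace bit-identically.
#'
#' @param cfg a [psc_synth_config()].
#' @return list with `trace` (a [trace()]) and `truth`, a data.frame with
#'   `onset_s` and `amplitude_pa` (signed magnitude, always positive).
#' @export
gen_psc_trace <- function(cfg) {
  check_that(inherits(cfg, "psc_synth_config"), "cfg must come from psc_synth_config()")
  n <- max(2L, round(cfg$duration_s * cfg$fs_hz))
  with_seed(cfg$seed, {
    t <- (seq_len(n) - 1) / cfg$fs_hz
    x <- numeric(n)
    if (cfg$drift_amp_pa > 0) {
      x <- x + cfg$drift_amp_pa * sin(2 * pi * t / cfg$drift_period_s)
    }
    if (cfg$drift_walk_sd_pa > 0) {
      x <- x + cumsum(stats::rnorm(n, 0, cfg$drift_walk_sd_pa))
    }
    if (cfg$noise_sd_pa > 0) x <- x + stats::rnorm(n, 0, cfg$noise_sd_pa)

    n_ev <- stats::rpois(1, cfg$event_rate_hz * cfg$duration_s)
    if (n_ev > 0) {
      onsets <- sort(stats::runif(n_ev, 0, cfg$duration_s))
      # lognormal with mean amp_mean_pa and CV amp_cv
      if (cfg$amp_cv > 0) {
        sdl <- sqrt(log(1 + cfg$amp_cv^2))
        ml <- log(cfg$amp_mean_pa) - sdl^2 / 2
        amps <- stats::rlnorm(n_ev, ml, sdl)
      } else {
        amps <- rep(cfg$amp_mean_pa, n_ev)
      }
      sign_ <- if (cfg$polarity == "inward") -1 else 1
      klen <- min(n, ceiling(8 * cfg$tau_decay_ms / 1000 * cfg$fs_hz))
      kt <- (seq_len(klen) - 1) / cfg$fs_hz
      kern <- psc_kernel(kt, cfg$tau_rise_ms, cfg$tau_decay_ms)
      for (i in seq_len(n_ev)) {
        i0 <- floor(onsets[i] * cfg$fs_hz) + 1L
        idx <- i0:min(n, i0 + klen - 1L)
        x[idx] <- x[idx] + sign_ * amps[i] * kern[seq_along(idx)]
      }
      truth <- data.frame(onset_s = onsets, amplitude_pa = amps)
    } else {
      truth <- data.frame(onset_s = numeric(0), amplitude_pa = numeric(0))
    }
    list(trace = trace(x, cfg$fs_hz, units = "pA",
                       meta = list(polarity = cfg$polarity)),
         truth = truth)
  })
}
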