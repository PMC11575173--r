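#' Configuration for synthetic spike trains
#'
#' @param duration_s recording length (s).
#' @param mode `"poisson"` (homogeneous Poisson thinned by a refractory
#'   period) or `"bursty"` (Poisson burst onsets, geometric spike counts,
#'   jittered intra-burst ISIs).
#' @param rate_hz mean rate (poisson mode) in Hz.
#' @param burst_rate_hz burst-onset rate (bursty mode).
#' @param spikes_per_burst_mean mean spikes per burst (geometric, >= 1).
#' @param intra_burst_isi_ms mean intra-burst inter-spike interval (ms).
#' @param isi_jitter_ms SD of intra-burst ISI jitter (ms).
#' @param refractory_ms absolute refractory period (ms).
#' @param seed RNG seed.
#' @return a `spike_synth_config` list.
#' @export
spike_synth_config <- function(duration_s = 600, mode = c("poisson", "bursty"),
                               rate_hz = 5, burst_rate_hz = 1,
                               spikes_per_burst_mean = 4,
                               intra_burst_isi_ms = 5, isi_jitter_ms = 0.5,
                               refractory_ms = 2, seed = NULL) {
  mode <- match.arg(mode)
  check_that(duration_s >= 0, "duration_s must be >= 0, got %g", duration_s)
  check_that(rate_hz > 0, "rate_hz must be > 0, got %g", rate_hz)
  check_that(refractory_ms >= 0, "refractory_ms must be >= 0, got %g", refractory_ms)
  structure(as.list(environment()), class = "spike_synth_config")
}

#' Generate a synthetic spike train
#'
#' @param cfg a [spike_synth_config()].
#' @return sorted numeric vector of spike times in seconds.
#' @export
gen_spike_train <- function(cfg) {
  check_that(inherits(cfg, "spike_synth_config"), "cfg must come from spike_synth_config()")
  if (cfg$duration_s == 0) return(numeric(0))
  with_seed(cfg$seed, {
    if (cfg$mode == "poisson") {
      n <- stats::rpois(1, cfg$rate_hz * cfg$duration_s)
      t <- sort(stats::runif(n, 0, cfg$duration_s))
      if (cfg$refractory_ms > 0 && length(t) > 1) {
        refr <- cfg$refractory_ms / 1000
        keep <- logical(length(t))
        last <- -Inf
        for (i in seq_along(t)) {
          if (t[i] - last >= refr) { keep[i] <- TRUE; last <- t[i] }
        }
        t <- t[keep]
      }
      t
    } else {
      n_bursts <- stats::rpois(1, cfg$burst_rate_hz * cfg$duration_s)
      onsets <- sort(stats::runif(n_bursts, 0, cfg$duration_s))
      t <- unlist(lapply(onsets, function(o) {
        n_sp <- 1 + stats::rgeom(1, 1 / max(1, cfg$spikes_per_burst_mean))
        isis <- abs(stats::rnorm(n_sp - 1, cfg$intra_burst_isi_ms,
                                 cfg$isi_jitter_ms)) / 1000
        isis <- pmax(isis, cfg$refractory_ms / 1000)
        o + c(0, cumsum(isis))
      }))
      sort(t[t <= cfg$duration_s])
    }
  })
}

# Biphasic extracellular spike template: narrow trough followed by a slower
# positive after-peak at `t2p_ms` after the trough.
spike_template <- function(t2p_ms, fs_hz = 30000, dur_ms = 3, trough_uv = 100) {
  t <- seq(0, dur_ms / 1000, by = 1 / fs_hz)
  t_trough <- 0.8 / 1000
  w_trough <- 0.1 / 1000
  t_peak <- t_trough + t2p_ms / 1000
  w_peak <- 0.25 * t2p_ms / 1000 + 0.05 / 1000
  y <- -trough_uv * exp(-(t - t_trough)^2 / (2 * w_trough^2)) +
    0.35 * trough_uv * exp(-(t - t_peak)^2 / (2 * w_peak^2))
  y
}

#' Generate mean unit waveforms of a given class
#'
#' Narrow-spiking templates have trough-to-peak times around 0.2-0.4 ms
#' (putative fast-spiking interneurons); wide-spiking around 0.6-1.0 ms
#' (putative projection neurons). Additive Gaussian noise on each waveform.
#'
#' @param class `"narrow"` or `"wide"`.
#' @param n number of waveforms.
#' @param noise_sd_uv additive noise SD (uV).
#' @param fs_hz waveform sampling rate (default 30 kHz).
#' @param seed RNG seed.
#' @return list of numeric waveform vectors (uV); attribute `fs_hz`.
#' @export
gen_unit_waveform <- function(class = c("narrow", "wide"), n, noise_sd_uv = 5,
                              fs_hz = 30000, seed = NULL) {
  class <- match.arg(class)
  check_that(n >= 0, "n must be >= 0")
  if (n == 0) return(structure(list(), fs_hz = fs_hz))
  rng <- if (class == "narrow") c(0.25, 0.38) else c(0.62, 0.95)
  with_seed(seed, {
    t2p <- stats::runif(n, rng[1], rng[2])
    out <- lapply(t2p, function(tp) {
      w <- spike_template(tp, fs_hz = fs_hz)
      if (noise_sd_uv > 0) w <- w + stats::rnorm(length(w), 0, noise_sd_uv)
      w
    })
    structure(out, fs_hz = fs_hz, true_t2p_ms = t2p)
  })
}
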