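#' Band-limited burst specification for synthetic LFP
#'
#' @param band_low_hz,band_high_hz band edges (Hz).
#' @param rate_per_min mean Poisson burst rate (events/min).
#' @param duration_ms_mean mean burst duration, defined as the full width at
#'   half maximum of the Gaussian envelope (ms).
#' @param amplitude_db peak envelope amplitude in dB over the band-limited
#'   background envelope.
#' @return a `burst_spec` list.
#' @export
burst_spec <- function(band_low_hz, band_high_hz, rate_per_min = 10,
                       duration_ms_mean = 300, amplitude_db = 8) {
  check_that(band_low_hz > 0 && band_high_hz > band_low_hz,
             "need 0 < band_low_hz < band_high_hz")
  check_that(rate_per_min >= 0, "rate_per_min must be >= 0")
  structure(as.list(environment()), class = "burst_spec")
}

#' Configuration for synthetic LFP
#'
#' A `1/f^alpha` background (inverse-FFT spectral synthesis with randomized
#' phases) with band-limited Gaussian-envelope oscillatory transients and
#' optional 50 Hz line noise.
#'
#' @param duration_s length (s).
#' @param fs_hz sampling rate.
#' @param background_exponent spectral exponent alpha of the `1/f^alpha`
#'   background (0 = white noise).
#' @param background_rms_uv RMS of the background (uV).
#' @param burst_specs list of [burst_spec()]s.
#' @param line_noise_50hz_db optional 50 Hz line amplitude, dB over the
#'   background RMS; `NULL` for none.
#' @param seed RNG seed.
#' @return an `lfp_synth_config` list.
#' @export
lfp_synth_config <- function(duration_s = 600, fs_hz = 1000,
                             background_exponent = 1.5, background_rms_uv = 50,
                             burst_specs = list(), line_noise_50hz_db = NULL,
                             seed = NULL) {
  check_that(duration_s > 0, "duration_s must be > 0")
  check_that(fs_hz > 0, "fs_hz must be > 0")
  for (bs in burst_specs) {
    check_that(inherits(bs, "burst_spec"), "burst_specs must be burst_spec() objects")
    check_that(bs$band_high_hz < fs_hz / 2,
               "burst band %g-%g Hz exceeds Nyquist %g Hz",
               bs$band_low_hz, bs$band_high_hz, fs_hz / 2)
  }
  structure(as.list(environment()), class = "lfp_synth_config")
}

# 1/f^alpha noise of unit RMS by inverse-FFT spectral synthesis.
powerlaw_noise <- function(n, alpha) {
  nf <- n %/% 2
  f <- seq_len(nf)
  amp <- f^(-alpha / 2)
  ph <- stats::runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = ph)
  full <- complex(real = numeric(n))
  full[2:(nf + 1)] <- spec
  if (n %% 2 == 0) {
    full[nf + 1] <- complex(real = amp[nf] * cos(ph[nf]))
    full[(nf + 2):n] <- Conj(spec[(nf - 1):1])
  } else {
    full[(nf + 2):n] <- Conj(spec[nf:1])
  }
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Generate a synthetic LFP trace with ground-truth oscillatory bursts
#'
#' @param cfg an [lfp_synth_config()].
#' @return list with `trace` (uV) and `truth`, a data.frame with one row per
#'   injected burst: `band_low_hz`, `band_high_hz`, `start_s`, `peak_s`,
#'   `end_s`, `duration_s`, `peak_freq_hz`, `amplitude_db`.
#' @export
gen_lfp <- function(cfg) {
  check_that(inherits(cfg, "lfp_synth_config"), "cfg must come from lfp_synth_config()")
  n <- round(cfg$duration_s * cfg$fs_hz)
  with_seed(cfg$seed, {
    x <- if (cfg$background_rms_uv > 0) {
      cfg$background_rms_uv * powerlaw_noise(n, cfg$background_exponent)
    } else numeric(n)
    t <- (seq_len(n) - 1) / cfg$fs_hz

    if (!is.null(cfg$line_noise_50hz_db) && cfg$background_rms_uv > 0) {
      a <- cfg$background_rms_uv * 10^(cfg$line_noise_50hz_db / 20)
      x <- x + a * sqrt(2) * sin(2 * pi * 50 * t)
    }

    rows <- list()
    for (bs in cfg$burst_specs) {
      n_b <- stats::rpois(1, bs$rate_per_min / 60 * cfg$duration_s)
      if (n_b == 0) next
      # reference envelope of the band-limited background
      bg_env <- if (cfg$background_rms_uv > 0) {
        bb <- butter_filtfilt(x, cfg$fs_hz, low = bs$band_low_hz, high = bs$band_high_hz)
        stats::median(Mod(hilbert_analytic(bb)))
      } else 1
      peaks <- sort(stats::runif(n_b, 0.05 * cfg$duration_s, 0.95 * cfg$duration_s))
      durs <- stats::rlnorm(n_b, log(bs$duration_ms_mean / 1000) - 0.02, 0.2)
      frs <- stats::runif(n_b,
                          bs$band_low_hz + 0.25 * (bs$band_high_hz - bs$band_low_hz),
                          bs$band_high_hz - 0.25 * (bs$band_high_hz - bs$band_low_hz))
      for (i in seq_len(n_b)) {
        a_peak <- bg_env * 10^(bs$amplitude_db / 20)
        sigma <- durs[i] / 2.355  # FWHM -> Gaussian SD
        lo <- max(1L, floor((peaks[i] - 4 * sigma) * cfg$fs_hz))
        hi <- min(n, ceiling((peaks[i] + 4 * sigma) * cfg$fs_hz))
        idx <- lo:hi
        tt <- t[idx] - peaks[i]
        x[idx] <- x[idx] + a_peak * exp(-tt^2 / (2 * sigma^2)) *
          cos(2 * pi * frs[i] * tt)
        rows[[length(rows) + 1L]] <- data.frame(
          band_low_hz = bs$band_low_hz, band_high_hz = bs$band_high_hz,
          start_s = peaks[i] - durs[i] / 2, peak_s = peaks[i],
          end_s = peaks[i] + durs[i] / 2, duration_s = durs[i],
          peak_freq_hz = frs[i], amplitude_db = bs$amplitude_db)
      }
    }
    truth <- if (length(rows)) do.call(rbind, rows) else
      data.frame(band_low_hz = numeric(0), band_high_hz = numeric(0),
                 start_s = numeric(0), peak_s = numeric(0), end_s = numeric(0),
                 duration_s = numeric(0), peak_freq_hz = numeric(0),
                 amplitude_db = numeric(0))
    truth <- truth[order(truth$peak_s), , drop = FALSE]
    rownames(truth) <- NULL
    list(trace = trace(x, cfg$fs_hz, units = "uV"), truth = truth)
  })
}
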