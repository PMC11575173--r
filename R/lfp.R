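#' Spectral analysis configuration
#'
#' @param segment_s segment length for PSD estimation (s, default 10).
#' @param tw multitaper time-bandwidth product (default 3).
#' @param k number of Slepian tapers (default 5; must satisfy `k <= 2*tw-1`).
#' @param norm_band normalization band (Hz, default 1-90).
#' @param line_exclusion band excluded from the normalization mean around
#'   the 50 Hz line (Hz, default 48-52).
#' @return a `spectral_config` list.
#' @export
spectral_config <- function(segment_s = 10, tw = 3, k = 5,
                            norm_band = c(1, 90), line_exclusion = c(48, 52)) {
  check_that(k <= 2 * tw - 1, "k (%d) must be <= 2*tw - 1 (%g)", k, 2 * tw - 1)
  check_that(segment_s > 0, "segment_s must be > 0")
  structure(as.list(environment()), class = "spectral_config")
}

#' Oscillatory burst detection configuration
#'
#' Dual-magnitude-threshold semantics: an event must exceed the background
#' envelope by `dbpeak` dB at its peak and extends bidirectionally to the
#' `dbend` dB crossings. `provenance_params` carries legacy wlBurst-style
#' settings for provenance; they do not affect the computation here.
#'
#' @param dbpeak peak threshold, dB over background (default 6).
#' @param dbend boundary threshold, dB over background (default 2).
#' @param min_duration_periods minimum event duration in periods of the band
#'   center frequency (default 1).
#' @param merge_gap_periods events closer than this many periods merge
#'   (default 0.5).
#' @param smooth_periods envelope smoothing (centered moving average) in
#'   periods of the band center frequency before thresholding (default 4);
#'   the raw analytic envelope of band-limited noise fluctuates strongly
#'   (Rayleigh), so unsmoothed thresholding fragments events and fires on
#'   noise.
#' @param provenance_params named list recorded for provenance.
#' @return a `burst_detect_config` list.
#' @export
burst_detect_config <- function(dbpeak = 6, dbend = 2, min_duration_periods = 1,
                                merge_gap_periods = 0.5, smooth_periods = 4,
                                provenance_params = list(type = "magdual",
                                                         qlong = 10, qdrop = 0.5,
                                                         qglitch = 1.0)) {
  check_that(dbpeak > dbend && dbend > 0, "need dbpeak > dbend > 0")
  structure(as.list(environment()), class = "burst_detect_config")
}

#' Preprocess raw wide-band voltage into an LFP trace
#'
#' Anti-aliased decimation to 1000 Hz followed by zero-phase band-pass
#' filtering from 1 to 475 Hz (high-pass and low-pass applied separately
#' for numerical stability near Nyquist).
#'
#' @param raw a [trace()] with `fs_hz >= 1000` (integer multiple of 1000).
#' @return LFP [trace()] at 1000 Hz.
#' @export
preprocess_lfp <- function(raw, target_fs = 1000, band = c(1, 475)) {
  check_that(is_trace(raw), "raw must be a trace")
  check_that(raw$fs_hz >= target_fs, "raw sampling rate %g below %g Hz", raw$fs_hz, target_fs)
  x <- raw$samples
  if (raw$fs_hz > target_fs) {
    fac <- raw$fs_hz / target_fs
    check_that(abs(fac - round(fac)) < 1e-9,
               "sampling rate %g not an integer multiple of %g", raw$fs_hz, target_fs)
    fac <- round(fac)
    x <- butter_filtfilt(x, raw$fs_hz, high = 0.4 * target_fs, order = 8)
    x <- x[seq(1, length(x), by = fac)]
  }
  x <- butter_filtfilt(x, target_fs, low = band[1])
  x <- butter_filtfilt(x, target_fs, high = band[2])
  trace(x, target_fs, units = raw$units, t0_s = raw$t0_s, meta = raw$meta)
}

#' Flag motion-artifact samples
#'
#' Helper producing an artifact mask: samples deviating more than
#' `threshold_sd` robust SDs from the trace median.
#'
#' @param tr LFP [trace()].
#' @param threshold_sd robust-SD threshold (default 8).
#' @return logical vector, one element per sample.
#' @export
flag_artifacts <- function(tr, threshold_sd = 8) {
  abs(tr$samples - stats::median(tr$samples)) > threshold_sd * robust_sd(tr$samples)
}

#' Cut an LFP into non-overlapping clean segments
#'
#' Contiguous `segment_s` windows; any window containing a masked sample is
#' dropped; a trailing remainder shorter than `segment_s` is discarded.
#'
#' @param tr LFP [trace()].
#' @param artifact_mask optional logical mask (per sample).
#' @param segment_s window length (s, default 10).
#' @return list of numeric segment vectors; attribute `n_dropped` counts
#'   artifact-dropped windows. Warns when everything is masked.
#' @export
segment_lfp <- function(tr, artifact_mask = NULL, segment_s = 10) {
  n_seg_len <- round(segment_s * tr$fs_hz)
  n <- length(tr$samples)
  n_win <- n %/% n_seg_len
  segs <- list()
  dropped <- 0L
  for (i in seq_len(n_win)) {
    idx <- ((i - 1) * n_seg_len + 1):(i * n_seg_len)
    if (!is.null(artifact_mask) && any(artifact_mask[idx])) {
      dropped <- dropped + 1L
      next
    }
    segs[[length(segs) + 1L]] <- tr$samples[idx]
  }
  if (length(segs) == 0) warning("all segments masked or trace shorter than one segment")
  structure(segs, n_dropped = dropped, fs_hz = tr$fs_hz)
}

# memoized taper computation
.taper_cache <- new.env(parent = emptyenv())
get_tapers <- function(n, nw, k) {
  key <- paste(n, nw, k, sep = "_")
  if (is.null(.taper_cache[[key]])) .taper_cache[[key]] <- dpss_tapers(n, nw, k)
  .taper_cache[[key]]
}

#' Multitaper power spectral density
#'
#' Per-segment multitaper estimate with `k` Slepian tapers at time-bandwidth
#' `tw`, averaged across tapers and then across segments. One-sided density;
#' frequency resolution is `1/segment_s` (0.1 Hz for 10-s segments).
#'
#' @param segments list of equal-length numeric vectors (e.g. from
#'   [segment_lfp()]), or a single numeric vector / [trace()].
#' @param fs_hz sampling rate; taken from the segments' attribute or trace
#'   when omitted.
#' @param cfg a [spectral_config()].
#' @return list of class `psd`: `freq_hz`, `power`, `n_segments`, `fs_hz`.
#' @export
multitaper_psd <- function(segments, fs_hz = NULL, cfg = spectral_config()) {
  if (is_trace(segments)) {
    fs_hz <- segments$fs_hz
    segments <- list(segments$samples)
  } else if (is.numeric(segments)) {
    segments <- list(segments)
  } else if (is.null(fs_hz)) {
    fs_hz <- attr(segments, "fs_hz")
  }
  check_that(!is.null(fs_hz), "fs_hz required")
  check_that(length(segments) >= 1, "no segments")
  n <- length(segments[[1]])
  check_that(all(lengths(segments) == n), "segments must have equal length")
  tap <- get_tapers(n, cfg$tw, cfg$k)
  n_freq <- n %/% 2 + 1
  freqs <- (seq_len(n_freq) - 1) * fs_hz / n
  acc <- numeric(n_freq)
  for (seg in segments) {
    seg <- seg - mean(seg)
    p <- numeric(n_freq)
    for (j in seq_len(cfg$k)) {
      X <- stats::fft(seg * tap[, j])[seq_len(n_freq)]
      p <- p + (Mod(X)^2) / fs_hz
    }
    acc <- acc + p / cfg$k
  }
  pow <- acc / length(segments)
  # one-sided scaling (double everything but DC and Nyquist)
  sc <- rep(2, n_freq); sc[1] <- 1
  if (n %% 2 == 0) sc[n_freq] <- 1
  structure(list(freq_hz = freqs, power = pow * sc,
                 n_segments = length(segments), fs_hz = fs_hz),
            class = "psd")
}

#' Normalize a PSD to its mean over a band
#'
#' Divides the power by its mean over `norm_band` (default 1-90 Hz),
#' excluding the 50 Hz line-exclusion band, so that the mean of the
#' normalized spectrum over that support is exactly 1. Compensates for
#' electrode-impedance differences across recordings.
#'
#' @param psd a [multitaper_psd()] result.
#' @param cfg a [spectral_config()].
#' @return normalized `psd` object (attribute `norm_factor` holds the
#'   divisor).
#' @export
normalize_psd <- function(psd, cfg = spectral_config()) {
  f <- psd$freq_hz
  support <- f >= cfg$norm_band[1] & f <= cfg$norm_band[2] &
    !(f >= cfg$line_exclusion[1] & f <= cfg$line_exclusion[2])
  check_that(any(support), "normalization band outside spectrum support")
  m <- mean(psd$power[support])
  check_that(is.finite(m) && m > 0, "degenerate spectrum: normalization mean is %g", m)
  psd$power <- psd$power / m
  attr(psd, "norm_factor") <- m
  psd
}

#' Mean band power of a PSD
#'
#' @param psd a `psd` object (normalized or not).
#' @param lo_hz,hi_hz band edges; mean power over `[lo, hi)`.
#' @return scalar mean power.
#' @export
band_power <- function(psd, lo_hz, hi_hz) {
  check_that(lo_hz >= min(psd$freq_hz) && hi_hz <= max(psd$freq_hz) + 1e-9,
             "band %g-%g Hz outside spectrum range", lo_hz, hi_hz)
  sel <- psd$freq_hz >= lo_hz & psd$freq_hz < hi_hz
  check_that(any(sel), "empty band")
  mean(psd$power[sel])
}

#' Canonical oscillation bands
#'
#' Beta 13-30 Hz, low gamma 30-60 Hz, high gamma 60-90 Hz.
#' @return named list of `c(lo, hi)` pairs.
#' @export
osc_bands <- function() {
  list(beta = c(13, 30), low_gamma = c(30, 60), high_gamma = c(60, 90))
}

#' Detect oscillatory burst events in a band
#'
#' Band-pass filters the LFP, takes the analytic-signal envelope in dB, and
#' estimates the background as the median envelope (robust to the bursts
#' themselves). Events are intervals where the envelope exceeds background
#' + `dbend` dB and reaches background + `dbpeak` dB at least once; events
#' closer than `merge_gap_periods` periods of the band center frequency are
#' merged, and events shorter than `min_duration_periods` periods are
#' discarded.
#'
#' @param tr LFP [trace()].
#' @param band `c(lo, hi)` in Hz.
#' @param cfg a [burst_detect_config()].
#' @return data.frame: `start_s`, `peak_s`, `end_s`, `duration_s`,
#'   `peak_freq_hz`, `peak_db_over_background`.
#' @export
detect_osc_bursts <- function(tr, band, cfg = burst_detect_config()) {
  fs <- tr$fs_hz
  check_that(band[2] < fs / 2, "band above Nyquist")
  bp <- butter_filtfilt(tr$samples, fs, low = band[1], high = band[2])
  an <- hilbert_analytic(bp)
  env_raw <- Mod(an)
  f_center_pre <- mean(band)
  env <- env_raw
  env_fine <- env_raw
  if (cfg$smooth_periods > 0) {
    env <- moving_average(env_raw, round(cfg$smooth_periods / f_center_pre * fs))
    env_fine <- moving_average(env_raw,
                               max(1L, round(cfg$smooth_periods / 2 / f_center_pre * fs)))
  }
  env_db <- 20 * log10(pmax(env, 1e-12))
  env_fine_db <- 20 * log10(pmax(env_fine, 1e-12))
  bg <- stats::median(env_db)
  bg_fine <- stats::median(env_fine_db)
  f_center <- mean(band)
  above_end <- env_db > bg + cfg$dbend
  if (!any(above_end)) return(empty_bursts())
  runs <- find_runs(above_end)
  # keep runs that reach the peak threshold
  peak_ok <- vapply(seq_len(nrow(runs)), function(i) {
    any(env_db[runs$start[i]:runs$end[i]] > bg + cfg$dbpeak)
  }, logical(1))
  runs <- runs[peak_ok, , drop = FALSE]
  if (nrow(runs) == 0) return(empty_bursts())
  # merge runs separated by small gaps
  gap_max <- cfg$merge_gap_periods / f_center * fs
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      if (runs$start[i] - merged$end[nrow(merged)] < gap_max) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
  }
  # refine event boundaries on the finer envelope: the heavier detection
  # smoothing suppresses noise crossings but widens events; start/end are
  # re-measured as dbend crossings of the half-smoothed envelope around the
  # event peak
  pad <- round(2 / f_center * fs)
  n_s <- length(env_fine_db)
  for (i in seq_len(nrow(merged))) {
    idx <- merged$start[i]:merged$end[i]
    i_pk <- idx[which.max(env_fine_db[idx])]
    lo <- i_pk
    lim_lo <- max(1L, merged$start[i] - pad)
    while (lo > lim_lo && env_fine_db[lo - 1L] > bg_fine + cfg$dbend) lo <- lo - 1L
    hi <- i_pk
    lim_hi <- min(n_s, merged$end[i] + pad)
    while (hi < lim_hi && env_fine_db[hi + 1L] > bg_fine + cfg$dbend) hi <- hi + 1L
    merged$start[i] <- lo
    merged$end[i] <- hi
  }
  min_len <- cfg$min_duration_periods / f_center * fs
  merged <- merged[(merged$end - merged$start + 1) >= min_len, , drop = FALSE]
  if (nrow(merged) == 0) return(empty_bursts())
  # instantaneous frequency for peak-frequency readout
  ph <- Arg(an)
  inst_f <- c(NA, diff(unwrap_phase(ph))) * fs / (2 * pi)
  out <- do.call(rbind, lapply(seq_len(nrow(merged)), function(i) {
    idx <- merged$start[i]:merged$end[i]
    i_pk <- idx[which.max(env_db[idx])]
    fr <- stats::median(inst_f[idx], na.rm = TRUE)
    data.frame(start_s = tr$t0_s + (merged$start[i] - 1) / fs,
               peak_s = tr$t0_s + (i_pk - 1) / fs,
               end_s = tr$t0_s + (merged$end[i] - 1) / fs,
               duration_s = (merged$end[i] - merged$start[i]) / fs,
               peak_freq_hz = fr,
               peak_db_over_background = env_db[i_pk] - bg)
  }))
  rownames(out) <- NULL
  out
}

empty_bursts <- function() {
  data.frame(start_s = numeric(0), peak_s = numeric(0), end_s = numeric(0),
             duration_s = numeric(0), peak_freq_hz = numeric(0),
             peak_db_over_background = numeric(0))
}

unwrap_phase <- function(p) {
  dp <- diff(p)
  dp <- dp - 2 * pi * round(dp / (2 * pi))
  c(p[1], p[1] + cumsum(dp))
}

#' Burst-event statistics
#'
#' Occurrence rate, mean duration and mean peak amplitude. The amplitude
#' statistic depends on electrode impedance and is reported for completeness
#' only; compare it across electrodes with caution.
#'
#' @param events data.frame from [detect_osc_bursts()].
#' @param analyzed_duration_s analyzed duration (s, > 0).
#' @return list: `rate_per_min`, `mean_duration_s`, `mean_amplitude_db`,
#'   `amplitude_impedance_dependent = TRUE`.
#' @export
burst_statistics <- function(events, analyzed_duration_s) {
  check_that(analyzed_duration_s > 0, "analyzed_duration_s must be > 0")
  n <- nrow(events)
  list(rate_per_min = n / analyzed_duration_s * 60,
       mean_duration_s = if (n) mean(events$duration_s) else NA_real_,
       mean_amplitude_db = if (n) mean(events$peak_db_over_background) else NA_real_,
       amplitude_impedance_dependent = TRUE)
}

# complex Morlet magnitude at one frequency via frequency-domain Gaussian
morlet_row <- function(X, freqs_fft, f0, n_cycles, n) {
  sigma_t <- n_cycles / (2 * pi * f0)
  H <- exp(-0.5 * (2 * pi * (freqs_fft - f0) * sigma_t)^2)
  H[freqs_fft < 0] <- 0
  Mod(stats::fft(X * 2 * H, inverse = TRUE) / n)
}

#' Event-aligned wavelet spectrogram
#'
#' Complex-Morlet (6 cycles) magnitude spectrogram in windows around event
#' peaks. Each event's spectrogram row (frequency) is divided by its own
#' maximum before averaging across events, so each frequency contributes on
#' a common 0-1 scale. Also returns the average band-filtered LFP aligned to
#' the same peaks.
#'
#' @param tr LFP [trace()].
#' @param event_peaks_s event peak times (s); must be non-empty.
#' @param freq_range `c(lo, hi)` Hz of the spectrogram axis.
#' @param window_s half-window around each peak (s).
#' @param n_freq number of frequency rows.
#' @param n_cycles Morlet width in cycles (default 6).
#' @param align_band optional `c(lo, hi)` band for the aligned-average
#'   filtered trace (defaults to `freq_range`).
#' @return list: `freq_hz`, `time_s` (relative to peak), `power` (freq x
#'   time, row maxima <= 1), `aligned_mean` (band-filtered average),
#'   `n_events`.
#' @export
event_aligned_spectrogram <- function(tr, event_peaks_s, freq_range,
                                      window_s = 0.5, n_freq = 30,
                                      n_cycles = 6, align_band = NULL) {
  check_that(length(event_peaks_s) > 0, "no events to align to")
  fs <- tr$fs_hz
  n <- length(tr$samples)
  half <- round(window_s * fs)
  centers <- round((event_peaks_s - tr$t0_s) * fs) + 1L
  ok <- centers - half >= 1 & centers + half <= n
  centers <- centers[ok]
  check_that(length(centers) > 0, "no events with a full window inside the trace")
  freqs <- seq(freq_range[1], freq_range[2], length.out = n_freq)
  X <- stats::fft(tr$samples)
  freqs_fft <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) * fs / n
  rel <- (-half):half
  P <- matrix(0, n_freq, length(rel))
  for (r in seq_len(n_freq)) {
    mag <- morlet_row(X, freqs_fft, freqs[r], n_cycles, n)
    for (ci in centers) {
      seg <- mag[(ci - half):(ci + half)]
      P[r, ] <- P[r, ] + seg / max(seg)
    }
  }
  P <- P / length(centers)
  if (is.null(align_band)) align_band <- freq_range
  bf <- butter_filtfilt(tr$samples, fs, low = align_band[1], high = align_band[2])
  am <- rowMeans(sapply(centers, function(ci) bf[(ci - half):(ci + half)]))
  list(freq_hz = freqs, time_s = rel / fs, power = P,
       aligned_mean = am, n_events = length(centers))
}

#' Band-power time course normalized to baseline
#'
#' Sliding-window band power (squared analytic envelope of the band-pass
#' filtered signal averaged per window), divided by its mean over the
#' declared baseline interval; a value of 1 is baseline level.
#'
#' @param tr LFP [trace()].
#' @param bands named list of `c(lo, hi)` bands (default [osc_bands()]).
#' @param window_s window length (s).
#' @param step_s step between window centers (s).
#' @param baseline_interval `c(t0, t1)` seconds defining baseline.
#' @return data.frame: `time_s` (window centers) plus one column per band.
#' @export
band_power_timecourse <- function(tr, bands = osc_bands(), window_s = 10,
                                  step_s = 5, baseline_interval) {
  fs <- tr$fs_hz
  n <- length(tr$samples)
  t <- trace_times(tr)
  starts <- seq(1, n - round(window_s * fs) + 1, by = round(step_s * fs))
  check_that(length(starts) > 0, "trace shorter than one window")
  centers <- t[starts] + window_s / 2
  base_sel <- t >= baseline_interval[1] & t <= baseline_interval[2]
  check_that(any(base_sel), "baseline interval empty")
  out <- data.frame(time_s = centers)
  for (bn in names(bands)) {
    b <- bands[[bn]]
    bp <- butter_filtfilt(tr$samples, fs, low = b[1], high = b[2])
    pow <- Mod(hilbert_analytic(bp))^2
    base <- mean(pow[base_sel])
    check_that(base > 0, "degenerate baseline power in band %s", bn)
    wlen <- round(window_s * fs)
    cs <- cumsum(c(0, pow))
    vals <- (cs[starts + wlen] - cs[starts]) / wlen
    out[[bn]] <- vals / base
  }
  out
}
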