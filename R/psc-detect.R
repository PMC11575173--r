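#' Detector configuration for spontaneous PSC detection
#'
#' The hybrid detector combines three complementary candidate generators on
#' the baseline-removed trace: (1) a slope method that accumulates negative
#' slopes computed in a 1 ms window (smoothed with a 0.2 ms moving average)
#' and thresholds the accumulated excursion; (2) a high-band amplitude method
#' that high-pass filters above 10 Hz and thresholds at 4.5 robust SD; and
#' (3) a multi-band amplitude method applying the same thresholding to
#' band-pass filtered versions with high cutoff fixed at 300 Hz and low
#' cutoffs spanning 2-20 Hz. The slope method is disabled for IPSCs, whose
#' slow rise it cannot capture. Candidates from all methods are merged
#' within `merge_tol_ms` and vetted on amplitude and rise-time bounds.
#'
#' All SD thresholds use the robust (MAD-based) SD, since event-containing
#' traces inflate the naive SD.
#'
#' @param slope_window_ms slope computation window (ms).
#' @param slope_smooth_ms slope smoothing window (ms).
#' @param slope_threshold_sd threshold on the accumulated negative-slope
#'   trace, in robust SDs of its nonzero values.
#' @param highband_cut_hz high-pass cutoff of the high-band method (Hz).
#' @param amp_threshold_sd amplitude threshold, in robust SDs of the
#'   filtered trace.
#' @param multiband_high_hz fixed high cutoff of the multi-band method (Hz).
#' @param multiband_low_hz_set low cutoffs of the multi-band method (Hz).
#' @param merge_tol_ms candidates closer than this merge into one event (ms).
#' @param min_amplitude_pa vetting: discard events smaller than this (pA).
#' @param rise_bounds_ms vetting: admissible 20-80% rise-time range (ms).
#' @param use_slope_method logical; turned off automatically for sIPSC.
#' @return a `detector_config` list.
#' @export
detector_config <- function(slope_window_ms = 1.0, slope_smooth_ms = 0.2,
                            slope_threshold_sd = 4, highband_cut_hz = 10,
                            amp_threshold_sd = 4.5, multiband_high_hz = 300,
                            multiband_low_hz_set = c(2, 5, 10, 20),
                            merge_tol_ms = 2, min_amplitude_pa = 0,
                            rise_bounds_ms = c(0.1, 10),
                            use_slope_method = TRUE) {
  check_that(slope_window_ms > 0 && slope_smooth_ms > 0, "slope windows must be > 0")
  check_that(amp_threshold_sd > 0 && slope_threshold_sd > 0, "thresholds must be > 0")
  check_that(merge_tol_ms > 0, "merge_tol_ms must be > 0")
  structure(as.list(environment()), class = "detector_config")
}

#' Remove slow baseline drift with a moving-median filter
#'
#' Subtracts the running median computed in a centered window (default 1 s);
#' window truncation handles the edges. Offsets and slow drift vanish while
#' millisecond-scale synaptic events survive.
#'
#' @param tr a [trace()].
#' @param window_s median window length in seconds (default 1).
#' @return baseline-removed [trace()] of identical length.
#' @export
remove_baseline <- function(tr, window_s = 1.0) {
  check_that(is_trace(tr), "tr must be a trace")
  k <- round(window_s * tr$fs_hz)
  check_that(k >= 3, "window_s x fs must span at least 3 samples, got %d", k)
  check_that(k <= length(tr$samples), "baseline window (%d samples) longer than trace (%d)",
             k, length(tr$samples))
  if (k %% 2 == 0) k <- k + 1L
  base <- stats::runmed(tr$samples, k, endrule = "median")
  trace(tr$samples - base, tr$fs_hz, units = tr$units, t0_s = tr$t0_s, meta = tr$meta)
}

# Candidate onsets where a mask of supra-threshold (negative-going) samples
# is TRUE; one candidate per run, at run start. Times in seconds.
runs_to_onsets <- function(mask, fs, t0 = 0) {
  if (!any(mask)) return(numeric(0))
  r <- find_runs(mask)
  t0 + (r$start - 1) / fs
}

#' Slope-based candidate detection (inward events)
#'
#' Computes the signal slope in a 1 ms window, smooths it with a 0.2 ms
#' moving average, zeroes positive slopes, accumulates negative slopes
#' within each negative run (cumulative sum reset at sign change), and
#' thresholds the accumulated excursion at `slope_threshold_sd` robust SDs
#' of the nonzero accumulated values. Expects the baseline-removed trace in
#' inward-negative convention.
#'
#' @param tr baseline-removed [trace()], inward events negative.
#' @param cfg a [detector_config()].
#' @return candidate onset times (s).
#' @export
detect_slope <- function(tr, cfg = detector_config()) {
  fs <- tr$fs_hz
  w <- max(2L, round(cfg$slope_window_ms / 1000 * fs))
  x <- tr$samples
  check_that(length(x) > w + 2, "trace shorter than slope window")
  slope <- c(numeric(w), (x[(w + 1):length(x)] - x[1:(length(x) - w)])) * fs / w
  slope <- moving_average(slope, round(cfg$slope_smooth_ms / 1000 * fs))
  neg <- pmin(slope, 0)
  # run-wise cumulative sum of negative slopes, reset at non-negative points
  cs <- cumsum(neg)
  zero_pos <- seq_along(neg) * (neg == 0)
  last_zero <- cummax(zero_pos)
  offset <- ifelse(last_zero > 0, cs[pmax(last_zero, 1L)], 0)
  acc <- cs - offset
  # robust scale of the accumulated excursions: each negative run contributes
  # its minimum (the full accumulated drop); threshold is in units of the
  # MAD-based robust SD of those excursions about zero
  run_id <- cumsum(c(TRUE, diff(neg < 0) != 0))
  is_neg <- neg < 0
  if (sum(is_neg) < 10) return(numeric(0))
  run_min <- tapply(acc[is_neg], run_id[is_neg], min)
  # noise scale of the accumulated excursions: with many runs the median
  # run excursion is noise-dominated; with only a few (sparse, clean traces)
  # the accumulated trace itself provides the floor
  scale_ <- if (length(run_min) >= 50) {
    1.4826 * stats::median(abs(run_min))
  } else {
    1.4826 * stats::median(abs(acc))
  }
  if (!is.finite(scale_)) return(numeric(0))
  thr <- max(cfg$slope_threshold_sd * scale_, 1e-6 * max(abs(acc)))
  hit <- names(run_min)[run_min < -thr]
  mask <- is_neg & (run_id %in% as.integer(hit))
  runs_to_onsets(mask, fs, tr$t0_s)
}

# Shared amplitude-threshold crossing detector on a filtered trace.
amp_candidates <- function(filtered, fs, t0, threshold_sd) {
  # floor at 5% of the largest excursion guards against numerically silent
  # traces, where the MAD collapses to the scale of zero-phase filter
  # sidelobes (about 2% of the event peak)
  thr <- max(threshold_sd * robust_sd(filtered), 0.05 * max(abs(filtered)))
  if (!is.finite(thr) || thr <= 0) return(numeric(0))
  runs_to_onsets(filtered < -thr, fs, t0)
}

#' High-band amplitude candidate detection
#'
#' Zero-phase high-pass above `highband_cut_hz` (default 10 Hz), then
#' threshold crossings at `amp_threshold_sd` (default 4.5) robust SDs of the
#' filtered trace in the inward (negative) direction.
#'
#' @inheritParams detect_slope
#' @return candidate onset times (s).
#' @export
detect_highband <- function(tr, cfg = detector_config()) {
  hp <- butter_filtfilt(tr$samples, tr$fs_hz, low = cfg$highband_cut_hz)
  amp_candidates(hp, tr$fs_hz, tr$t0_s, cfg$amp_threshold_sd)
}

#' Multi-band amplitude candidate detection
#'
#' Repeats the amplitude thresholding on band-pass filtered versions of the
#' signal with the high cutoff fixed at 300 Hz and low cutoffs spanning
#' 2-20 Hz; per-band hits within `merge_tol_ms` collapse to one candidate.
#'
#' @inheritParams detect_slope
#' @return candidate onset times (s).
#' @export
detect_multiband <- function(tr, cfg = detector_config()) {
  check_that(cfg$multiband_high_hz < tr$fs_hz / 2,
             "multiband high cutoff %g Hz at or above Nyquist", cfg$multiband_high_hz)
  cand <- unlist(lapply(cfg$multiband_low_hz_set, function(lo) {
    bp <- butter_filtfilt(tr$samples, tr$fs_hz, low = lo, high = cfg$multiband_high_hz)
    amp_candidates(bp, tr$fs_hz, tr$t0_s, cfg$amp_threshold_sd)
  }))
  merge_times(sort(cand), cfg$merge_tol_ms / 1000)
}

# Collapse sorted times closer than tol to the earliest of each cluster.
merge_times <- function(times, tol_s) {
  if (length(times) <= 1) return(times)
  keep <- c(TRUE, diff(times) > tol_s)
  cluster <- cumsum(keep)
  as.numeric(tapply(times, cluster, min))
}

#' Combine per-method candidates into a deduplicated onset list
#'
#' Union of all methods' candidates; candidates within `merge_tol_ms` of
#' each other collapse to one event at the earliest time, recording which
#' methods contributed (`detected_by` provenance).
#'
#' @param per_method named list of candidate time vectors, e.g.
#'   `list(slope = ..., highband = ..., multiband = ...)`.
#' @param cfg a [detector_config()].
#' @return data.frame with `onset_s` and `detected_by` (comma-separated).
#' @export
combine_candidates <- function(per_method, cfg = detector_config()) {
  methods <- rep(names(per_method), lengths(per_method))
  times <- unlist(per_method, use.names = FALSE)
  if (length(times) == 0) {
    return(data.frame(onset_s = numeric(0), detected_by = character(0)))
  }
  o <- order(times)
  times <- times[o]; methods <- methods[o]
  cluster <- cumsum(c(TRUE, diff(times) > cfg$merge_tol_ms / 1000))
  onset <- as.numeric(tapply(times, cluster, min))
  by <- vapply(split(methods, cluster),
               function(m) paste(sort(unique(m)), collapse = ","), "")
  data.frame(onset_s = onset, detected_by = unname(by))
}

#' Measure amplitude and kinetics of detected events
#'
#' For each onset: local baseline = median of the 2 ms pre-onset; amplitude
#' = |extremum - baseline| within a 10 ms post-onset search window; 20-80%
#' rise time by linear interpolation of the rising phase; decay time
#' constant by single-exponential fit from the peak (fit failure leaves a
#' missing value, the event is retained). Overlapping events truncate each
#' other's windows.
#'
#' @param tr baseline-removed [trace()], inward-negative convention.
#' @param onsets event onset times (s).
#' @param search_ms peak search window after onset (ms).
#' @param baseline_ms pre-onset baseline window (ms).
#' @return data.frame with `onset_s`, `peak_s`, `amplitude_pa`,
#'   `rise_20_80_ms`, `decay_tau_ms`.
#' @export
measure_events <- function(tr, onsets, search_ms = 10, baseline_ms = 2) {
  fs <- tr$fs_hz
  x <- tr$samples
  n <- length(x)
  check_that(all(onsets >= tr$t0_s & onsets <= tr$t0_s + (n - 1) / fs),
             "event onset outside trace")
  onsets <- sort(onsets)
  res <- lapply(seq_along(onsets), function(i) {
    i_on <- floor((onsets[i] - tr$t0_s) * fs) + 1L
    next_on <- if (i < length(onsets)) {
      floor((onsets[i + 1] - tr$t0_s) * fs)
    } else n
    i_b0 <- max(1L, i_on - round(baseline_ms / 1000 * fs))
    baseline <- stats::median(x[i_b0:max(i_b0, i_on - 1L)])
    i_hi <- min(n, i_on + round(search_ms / 1000 * fs), next_on)
    if (i_hi <= i_on) i_hi <- min(n, i_on + 1L)
    seg <- x[i_on:i_hi]
    i_pk <- i_on + which.min(seg) - 1L   # inward-negative extremum
    amp <- baseline - x[i_pk]
    # 20-80% rise by interpolating crossings on the rising phase
    rise <- NA_real_
    if (i_pk > i_on && amp > 0) {
      y <- baseline - x[i_on:i_pk]       # 0 .. amp, increasing toward peak
      t20 <- crossing_time(y, 0.2 * amp)
      t80 <- crossing_time(y, 0.8 * amp)
      if (!is.na(t20) && !is.na(t80) && t80 > t20) {
        rise <- (t80 - t20) / fs * 1000
      }
    }
    # decay tau by single-exponential fit, peak to window end
    tau <- NA_real_
    i_dend <- min(n, i_pk + round(8 * search_ms / 1000 * fs), next_on)
    if (i_dend - i_pk >= round(0.001 * fs) && amp > 0) {
      yd <- baseline - x[i_pk:i_dend]
      td <- (seq_along(yd) - 1) / fs
      fit <- tryCatch(
        stats::nls(yd ~ A * exp(-td / k), start = list(A = amp, k = 0.005),
                   control = stats::nls.control(warnOnly = TRUE)),
        error = function(e) NULL)
      if (!is.null(fit)) {
        k <- stats::coef(fit)[["k"]]
        if (is.finite(k) && k > 0 && k < 1) tau <- k * 1000
      }
    }
    data.frame(onset_s = onsets[i], peak_s = tr$t0_s + (i_pk - 1) / fs,
               amplitude_pa = amp, rise_20_80_ms = rise, decay_tau_ms = tau)
  })
  do.call(rbind, res)
}

# First index (fractional, 1-based) where the increasing-ish vector y
# crosses level; linear interpolation between bracketing samples.
crossing_time <- function(y, level) {
  above <- which(y >= level)
  if (length(above) == 0) return(NA_real_)
  j <- above[1]
  if (j == 1) return(0)
  frac <- (level - y[j - 1]) / (y[j] - y[j - 1])
  (j - 2) + frac
}

#' Hybrid detection of spontaneous EPSC/IPSC events
#'
#' Full pipeline: baseline removal (1 s moving median), candidate generation
#' by the slope, high-band and multi-band methods, union with deduplication,
#' event measurement, and automated vetting (minimum amplitude, rise-time
#' bounds). sIPSC traces (outward events) are sign-flipped internally and
#' the slope method is disabled for them.
#'
#' @param tr raw [trace()] in pA.
#' @param modality `"sEPSC"` (inward events) or `"sIPSC"` (outward).
#' @param cfg a [detector_config()].
#' @param baseline_window_s moving-median window (s).
#' @return data.frame of events: `onset_s`, `peak_s`, `amplitude_pa`
#'   (positive magnitude), `rise_20_80_ms`, `decay_tau_ms`, `detected_by`.
#' @export
detect_psc <- function(tr, modality = c("sEPSC", "sIPSC"),
                       cfg = detector_config(), baseline_window_s = 1.0) {
  modality <- match.arg(modality)
  bl <- remove_baseline(tr, baseline_window_s)
  if (modality == "sIPSC") {
    bl$samples <- -bl$samples   # outward events -> inward-negative convention
  }
  use_slope <- cfg$use_slope_method && modality == "sEPSC"
  cand <- list(
    highband = detect_highband(bl, cfg),
    multiband = detect_multiband(bl, cfg)
  )
  if (use_slope) cand$slope <- detect_slope(bl, cfg)
  comb <- combine_candidates(cand, cfg)
  if (nrow(comb) == 0) {
    return(cbind(data.frame(onset_s = numeric(0), peak_s = numeric(0),
                            amplitude_pa = numeric(0), rise_20_80_ms = numeric(0),
                            decay_tau_ms = numeric(0)),
                 data.frame(detected_by = character(0))))
  }
  # automated vetting in place of manual inspection: a candidate must exceed
  # the amplitude threshold in the widest analysis band (lowest low cutoff
  # to multiband_high_hz), where event energy is concentrated and noise is
  # smallest; plus amplitude floor and rise-time bounds
  bp <- butter_filtfilt(bl$samples, bl$fs_hz,
                        low = min(cfg$multiband_low_hz_set),
                        high = cfg$multiband_high_hz)
  band_thr <- cfg$amp_threshold_sd * robust_sd(bp)
  n <- length(bp)
  win <- round(0.010 * bl$fs_hz)
  band_amp <- vapply(comb$onset_s, function(on) {
    i0 <- floor((on - bl$t0_s) * bl$fs_hz) + 1L
    -min(bp[i0:min(n, i0 + win)])
  }, numeric(1))
  comb <- comb[band_amp >= band_thr, , drop = FALSE]
  # refine each surviving candidate to the event onset proper: locate the
  # band-filtered extremum after the candidate, then walk back to the 10%
  # rise point; candidates from different methods that refine to the same
  # event collapse in a second merge pass
  if (nrow(comb) > 0) {
    # label each candidate with the sub-threshold excursion of the band
    # trace containing its extremum: candidates inside one excursion (e.g.
    # re-crossings during a slow decay) are the same event
    exc <- bp < -0.5 * band_thr
    exc_id <- cumsum(c(TRUE, diff(exc) != 0)) * exc   # 0 outside excursions
    info <- lapply(comb$onset_s, function(on) {
      i0 <- floor((on - bl$t0_s) * bl$fs_hz) + 1L
      i_ext <- i0 + which.min(bp[i0:min(n, i0 + win)]) - 1L
      lvl <- 0.1 * bp[i_ext]
      back_lim <- max(1L, i_ext - win)
      j <- i_ext
      while (j > back_lim && bp[j] < lvl) j <- j - 1L
      c(ref = bl$t0_s + (j - 1) / bl$fs_hz, run = exc_id[i_ext])
    })
    ref <- vapply(info, `[[`, numeric(1), "ref")
    run <- vapply(info, `[[`, numeric(1), "run")
    o <- order(ref)
    ref <- ref[o]; by <- comb$detected_by[o]; run <- run[o]
    same_run <- run > 0 & c(FALSE, run[-1] == run[-length(run)])
    cl <- cumsum((c(TRUE, diff(ref) > cfg$merge_tol_ms / 1000)) & !same_run)
    comb <- data.frame(
      onset_s = as.numeric(tapply(ref, cl, min)),
      detected_by = vapply(split(by, cl), function(m) {
        paste(sort(unique(unlist(strsplit(m, ",")))), collapse = ",")
      }, ""))
  }
  if (nrow(comb) == 0) {
    return(cbind(data.frame(onset_s = numeric(0), peak_s = numeric(0),
                            amplitude_pa = numeric(0), rise_20_80_ms = numeric(0),
                            decay_tau_ms = numeric(0)),
                 data.frame(detected_by = character(0))))
  }
  ev <- measure_events(bl, comb$onset_s)
  ev$detected_by <- comb$detected_by[match(ev$onset_s, comb$onset_s)]
  keep <- ev$amplitude_pa >= cfg$min_amplitude_pa &
    (is.na(ev$rise_20_80_ms) |
       (ev$rise_20_80_ms >= cfg$rise_bounds_ms[1] &
          ev$rise_20_80_ms <= cfg$rise_bounds_ms[2]))
  ev <- ev[keep, , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Event frequency
#'
#' @param events data.frame of events (or a count).
#' @param analyzed_duration_s analyzed duration (s, > 0).
#' @return frequency in Hz.
#' @export
event_frequency <- function(events, analyzed_duration_s) {
  check_that(analyzed_duration_s > 0, "analyzed_duration_s must be > 0")
  n <- if (is.data.frame(events)) nrow(events) else as.numeric(events)
  n / analyzed_duration_s
}

#' Match detected events to ground truth
#'
#' Greedy nearest matching of detected onsets to true onsets within a time
#' tolerance; each truth matches at most one detection.
#'
#' @param detected_s,truth_s onset times (s).
#' @param tol_ms matching tolerance (ms, default 2).
#' @return list with `recall`, `precision`, `n_matched`.
#' @export
match_events <- function(detected_s, truth_s, tol_ms = 2) {
  tol <- tol_ms / 1000
  used <- logical(length(detected_s))
  n_match <- 0L
  for (t in truth_s) {
    d <- abs(detected_s - t)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= tol) {
      used[j] <- TRUE
      n_match <- n_match + 1L
    }
  }
  list(
    recall = if (length(truth_s)) n_match / length(truth_s) else NA_real_,
    precision = if (length(detected_s)) n_match / length(detected_s) else NA_real_,
    n_matched = n_match
  )
}
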