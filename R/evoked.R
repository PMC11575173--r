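#' Per-pulse peak amplitudes from an evoked train
#'
#' For each stimulus: blank `artifact_blank_ms` after the stimulus, take the
#' local baseline as the median of the 2 ms pre-stimulus, and measure the
#' amplitude as |extremum - baseline| within the remaining inter-pulse
#' window. Re-measuring the baseline per pulse compensates for overlapping
#' decays of preceding responses. When several sweeps are supplied they are
#' averaged first.
#'
#' @param tr a [trace()] (single sweep) or list of traces (sweeps, averaged).
#' @param stim_times_s ascending stimulus times (s).
#' @param modality `"EPSC"` (inward, negative peaks) or `"IPSC"` (outward).
#' @param artifact_blank_ms post-stimulus blanking (ms, default 1).
#' @param baseline_ms pre-stimulus baseline window (ms).
#' @return numeric vector of per-pulse amplitudes (pA, magnitudes).
#' @export
extract_pulse_amplitudes <- function(tr, stim_times_s,
                                     modality = c("EPSC", "IPSC"),
                                     artifact_blank_ms = 1, baseline_ms = 2) {
  modality <- match.arg(modality)
  if (is.list(tr) && !is_trace(tr)) {
    fs <- tr[[1]]$fs_hz
    m <- rowMeans(sapply(tr, function(s) s$samples))
    tr <- trace(m, fs, units = tr[[1]]$units, t0_s = tr[[1]]$t0_s)
  }
  check_that(is_trace(tr), "tr must be a trace or list of traces")
  check_that(length(stim_times_s) >= 2, "need at least 2 stimuli")
  check_that(!is.unsorted(stim_times_s, strictly = TRUE), "stimulus times must ascend")
  fs <- tr$fs_hz
  n <- length(tr$samples)
  t_end <- tr$t0_s + (n - 1) / fs
  check_that(all(stim_times_s >= tr$t0_s & stim_times_s <= t_end),
             "stimulus outside trace")
  x <- if (modality == "IPSC") -tr$samples else tr$samples
  # light smoothing (~0.3 ms) trims the positive noise bias of the
  # extremum search without blunting the peak
  x <- moving_average(x, max(1L, round(3e-4 * fs)))
  n_p <- length(stim_times_s)
  ipi <- stats::median(diff(stim_times_s))
  vapply(seq_len(n_p), function(k) {
    i_st <- floor((stim_times_s[k] - tr$t0_s) * fs) + 1L
    i_b0 <- max(1L, i_st - round(baseline_ms / 1000 * fs))
    baseline <- stats::median(x[i_b0:max(i_b0, i_st - 1L)])
    i_lo <- min(n, i_st + round(artifact_blank_ms / 1000 * fs))
    win_end <- if (k < n_p) stim_times_s[k + 1] else stim_times_s[k] + ipi
    i_hi <- min(n, floor((win_end - tr$t0_s) * fs))
    if (i_hi <= i_lo) return(0)
    max(0, baseline - min(x[i_lo:i_hi]))   # inward-negative extremum
  }, numeric(1))
}

#' Normalize a train to its first pulse
#'
#' @param raw per-pulse amplitudes; first must be > 0.
#' @return amplitudes divided by the first (first element exactly 1).
#' @export
normalize_train <- function(raw) {
  check_that(length(raw) >= 2, "need at least 2 pulses")
  check_that(is.finite(raw[1]) && raw[1] > 0,
             "first-pulse amplitude must be > 0, got %g", raw[1])
  raw / raw[1]
}

#' Classify a normalized train as depressing / facilitating / neutral
#'
#' Depressing when the mean of pulses 2..n falls below `1 - delta`,
#' facilitating above `1 + delta`, neutral otherwise.
#'
#' @param normalized output of [normalize_train()].
#' @param delta neutrality margin (default 0.05).
#' @return one of `"depressing"`, `"facilitating"`, `"neutral"`.
#' @export
classify_stp <- function(normalized, delta = 0.05) {
  m <- mean(normalized[-1])
  if (m < 1 - delta) "depressing" else if (m > 1 + delta) "facilitating" else "neutral"
}

#' Short-term-plasticity profile of an evoked recording
#'
#' @inheritParams extract_pulse_amplitudes
#' @param delta neutrality margin for classification.
#' @return list with `raw_amplitudes_pa`, `normalized_amplitudes`, `ppr`
#'   (pulse 2 / pulse 1) and `classification`.
#' @export
stp_profile <- function(tr, stim_times_s, modality = c("EPSC", "IPSC"),
                        artifact_blank_ms = 1, delta = 0.05) {
  raw <- extract_pulse_amplitudes(tr, stim_times_s, modality, artifact_blank_ms)
  norm <- normalize_train(raw)
  list(raw_amplitudes_pa = raw, normalized_amplitudes = norm,
       ppr = norm[2], classification = classify_stp(norm, delta))
}
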