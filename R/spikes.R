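#' Single-unit container
#'
#' @param spike_times_s strictly increasing spike times (s).
#' @param mean_waveform_uv mean extracellular waveform (uV).
#' @param waveform_fs_hz waveform sampling rate (default 30 kHz).
#' @param recording_duration_s recording length (s).
#' @return object of class `spike_unit`.
#' @export
spike_unit <- function(spike_times_s, mean_waveform_uv = NULL,
                       waveform_fs_hz = 30000, recording_duration_s = NULL) {
  spike_times_s <- as.numeric(spike_times_s)
  if (length(spike_times_s) > 1) {
    check_that(!is.unsorted(spike_times_s, strictly = TRUE),
               "spike times must be strictly increasing")
  }
  if (is.null(recording_duration_s)) {
    recording_duration_s <- if (length(spike_times_s)) max(spike_times_s) else 0
  }
  check_that(all(spike_times_s >= 0 & spike_times_s <= recording_duration_s),
             "spike times outside [0, duration]")
  structure(list(spike_times_s = spike_times_s,
                 mean_waveform_uv = mean_waveform_uv,
                 waveform_fs_hz = waveform_fs_hz,
                 recording_duration_s = recording_duration_s),
            class = "spike_unit")
}

#' Mean firing rate
#' @param unit a [spike_unit()].
#' @return rate in Hz.
#' @export
mean_rate <- function(unit) {
  check_that(unit$recording_duration_s > 0, "recording duration must be > 0")
  length(unit$spike_times_s) / unit$recording_duration_s
}

#' Spike-train autocorrelogram
#'
#' Counts of spike-pair lags in `(0, max_lag_ms]` at `bin_ms` resolution;
#' zero-lag self-pairs are excluded. One-sided (positive lags); equivalent
#' to brute-force enumeration of all ordered pairs.
#'
#' @param unit a [spike_unit()] (or numeric spike times).
#' @param bin_ms bin width (ms, default 1).
#' @param max_lag_ms maximum lag (ms, default 50).
#' @return list of class `acg`: `bin_edges_ms` (length bins+1), `counts`,
#'   `n_spikes`.
#' @export
autocorrelogram <- function(unit, bin_ms = 1, max_lag_ms = 50) {
  t <- if (inherits(unit, "spike_unit")) unit$spike_times_s else as.numeric(unit)
  edges <- seq(0, max_lag_ms, by = bin_ms)
  counts <- integer(length(edges) - 1)
  n <- length(t)
  if (n >= 2) {
    max_lag <- max_lag_ms / 1000
    # for each spike, lags to all later spikes within max_lag
    j_hi <- findInterval(t + max_lag, t)
    for (i in seq_len(n - 1)) {
      if (j_hi[i] > i) {
        lags <- (t[(i + 1):j_hi[i]] - t[i]) * 1000
        lags <- lags[lags > 0 & lags <= max_lag_ms]
        if (length(lags)) {
          b <- pmin(length(counts), floor((lags - 1e-12) / bin_ms) + 1L)
          tb <- tabulate(b, nbins = length(counts))
          counts <- counts + tb
        }
      }
    }
  }
  structure(list(bin_edges_ms = edges, counts = counts, n_spikes = n),
            class = "acg")
}

#' Burst index from an autocorrelogram
#'
#' Head = sum of counts with lags in (2, 10] ms, tail = sum in (35, 50] ms;
#' index = (head - tail) / (head + tail), in [-1, 1]. For a homogeneous
#' Poisson train the autocorrelogram is flat, so the expected index is
#' (8 - 15) / (8 + 15) = -7/23.
#'
#' @param acg an [autocorrelogram()].
#' @param head_ms,tail_ms half-open lag windows (ms).
#' @return list: `head_sum`, `tail_sum`, `index` (NA when head + tail = 0).
#' @export
burst_index <- function(acg, head_ms = c(2, 10), tail_ms = c(35, 50)) {
  mids <- (head(acg$bin_edges_ms, -1) + tail(acg$bin_edges_ms, -1)) / 2
  # half-open windows (lo, hi]: a 1-ms bin belongs to the window of its
  # upper edge
  hi_edge <- acg$bin_edges_ms[-1]
  head_sum <- sum(acg$counts[hi_edge > head_ms[1] & hi_edge <= head_ms[2]])
  tail_sum <- sum(acg$counts[hi_edge > tail_ms[1] & hi_edge <= tail_ms[2]])
  idx <- if (head_sum + tail_sum == 0) NA_real_ else {
    (head_sum - tail_sum) / (head_sum + tail_sum)
  }
  list(head_sum = head_sum, tail_sum = tail_sum, index = idx)
}

#' Waveform shape features
#'
#' Trough-to-peak time (global trough to the subsequent positive peak),
#' trough half-width, and peak/trough amplitude ratio.
#'
#' @param w numeric mean waveform (uV).
#' @param fs_hz waveform sampling rate.
#' @return list: `trough_to_peak_ms`, `half_width_ms`, `peak_trough_ratio`.
#' @export
waveform_features <- function(w, fs_hz = 30000) {
  # light smoothing (~0.2 ms) stabilizes extrema locations against noise
  w <- moving_average(w, 2L * floor(fs_hz * 1e-4) + 1L)
  i_tr <- which.min(w)
  check_that(i_tr < length(w) && min(w) < 0,
             "waveform not biphasic: no trough followed by a peak")
  post <- w[(i_tr + 1):length(w)]
  i_pk <- i_tr + which.max(post)
  check_that(w[i_pk] > 0, "waveform not biphasic: no positive after-peak")
  t2p <- (i_pk - i_tr) / fs_hz * 1000
  half <- w[i_tr] / 2
  below <- which(w <= half)
  hw <- (max(below) - min(below) + 1) / fs_hz * 1000
  list(trough_to_peak_ms = t2p, half_width_ms = hw,
       peak_trough_ratio = abs(w[i_pk] / w[i_tr]))
}

#' Unit quality metrics
#'
#' Amplitude = waveform trough magnitude (uV); ISI violation = percentage of
#' inter-spike intervals shorter than the refractory period; SNR = waveform
#' peak-to-peak over the residual noise SD estimated from the waveform tails;
#' noise cutoff = ratio of the amplitude-histogram height at its low-
#' amplitude edge to the histogram peak (truncation indicator, 0-1 scale).
#'
#' @param unit a [spike_unit()].
#' @param refractory_ms refractory period for ISI violations (ms, default 2).
#' @param spike_amplitudes_uv optional per-spike amplitudes for the noise-
#'   cutoff histogram; when missing the cutoff is 0 (no truncation evidence).
#' @return list: `amplitude_uv`, `isi_violation_pct`, `noise_cutoff`, `snr`.
#' @export
compute_quality <- function(unit, refractory_ms = 2, spike_amplitudes_uv = NULL) {
  w <- unit$mean_waveform_uv
  amp <- if (is.null(w)) NA_real_ else abs(min(w))
  isis <- diff(unit$spike_times_s) * 1000
  isi_viol <- if (length(isis)) 100 * mean(isis < refractory_ms) else 0
  snr <- NA_real_
  if (!is.null(w)) {
    n_tail <- max(3L, round(length(w) * 0.1))
    resid <- c(head(w, n_tail) - mean(head(w, n_tail)),
               tail(w, n_tail) - mean(tail(w, n_tail)))
    noise_sd <- stats::sd(resid)
    snr <- if (is.finite(noise_sd) && noise_sd > 0) diff(range(w)) / noise_sd else Inf
    if (diff(range(w)) == 0) snr <- 0
  }
  cutoff <- 0
  if (!is.null(spike_amplitudes_uv) && length(spike_amplitudes_uv) >= 20) {
    h <- graphics::hist(spike_amplitudes_uv, breaks = 30, plot = FALSE)
    cutoff <- h$counts[1] / max(h$counts)
  }
  list(amplitude_uv = amp, isi_violation_pct = isi_viol,
       noise_cutoff = cutoff, snr = snr)
}

#' Unit quality-control gate
#'
#' Pass iff amplitude > 50 uV, ISI violation < 0.5 (percent), noise cutoff
#' < 0.5 and SNR > 2.5.
#'
#' @param qm output of [compute_quality()].
#' @return list: `pass` (logical) and `failed` (character vector of
#'   criteria that failed).
#' @export
quality_pass <- function(qm) {
  failed <- character(0)
  if (!(is.finite(qm$amplitude_uv) && qm$amplitude_uv > 50)) failed <- c(failed, "amplitude")
  if (!(qm$isi_violation_pct < 0.5)) failed <- c(failed, "isi_violation")
  if (!(qm$noise_cutoff < 0.5)) failed <- c(failed, "noise_cutoff")
  if (!(is.finite(qm$snr) && qm$snr > 2.5)) failed <- c(failed, "snr")
  list(pass = length(failed) == 0, failed = failed)
}

#' Classify units into putative fast-spiking interneurons vs projection neurons
#'
#' Unsupervised 2-means split on standardized waveform/rate features
#' (trough-to-peak, half-width, log firing rate). The cluster with the
#' smaller mean trough-to-peak is labeled the putative PV interneuron class
#' (narrow spikes, higher rates); the other the putative SPN class.
#'
#' @param features data.frame with columns `trough_to_peak_ms`,
#'   `half_width_ms`, `rate_hz` (one row per unit).
#' @param seed RNG seed for the k-means initialization.
#' @return character vector of labels `"putative_PV_IN"` / `"putative_SPN"`,
#'   one per row of `features`.
#' @export
classify_units <- function(features, seed = 1) {
  check_that(nrow(features) >= 4, "insufficient units: need >= 4, got %d", nrow(features))
  X <- cbind(features$trough_to_peak_ms, features$half_width_ms,
             log(pmax(features$rate_hz, 1e-3)))
  sds <- apply(X, 2, stats::sd)
  check_that(any(sds > 0), "all units identical: classification refused")
  X <- scale(X[, sds > 0, drop = FALSE])
  km <- with_seed(seed, stats::kmeans(X, centers = 2, nstart = 25))
  mean_t2p <- tapply(features$trough_to_peak_ms, km$cluster, mean)
  narrow_cluster <- as.integer(names(which.min(mean_t2p)))
  ifelse(km$cluster == narrow_cluster, "putative_PV_IN", "putative_SPN")
}
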