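#!/usr/bin/env Rscript
# LFP analysis of the simulated recording: multitaper spectrum (TW = 3,
# K = 5, 10-s segments) normalized over 1-90 Hz avoiding 50 Hz, band powers,
# beta burst-event detection scored against injected truth, and the
# event-aligned wavelet spectrogram.

suppressMessages(library(striatools))
out <- "results"
lfp <- read_trace(file.path(out, "lfp_trace"))
truth <- read.csv(file.path(out, "lfp_burst_truth.csv"))

mask <- flag_artifacts(lfp)
segs <- segment_lfp(lfp, mask)
psd <- normalize_psd(multitaper_psd(segs))
keep <- psd$freq_hz <= 120
write.csv(data.frame(freq_hz = psd$freq_hz[keep], norm_power = psd$power[keep]),
          file.path(out, "lfp_psd.csv"), row.names = FALSE)
bp <- vapply(osc_bands(), function(b) band_power(psd, b[1], b[2]), numeric(1))
message(sprintf("segments used: %d (dropped %d); band powers: beta %.2f, low gamma %.2f, high gamma %.2f",
                length(segs), attr(segs, "n_dropped"), bp[1], bp[2], bp[3]))

ev <- detect_osc_bursts(lfp, c(13, 30))
write.csv(ev, file.path(out, "lfp_beta_events.csv"), row.names = FALSE)
st <- burst_statistics(ev, length(lfp$samples) / lfp$fs_hz)
message(sprintf("beta events: %d detected (%d injected); %.2f/min, mean duration %.0f ms",
                nrow(ev), nrow(truth), st$rate_per_min, 1000 * st$mean_duration_s))

sp <- event_aligned_spectrogram(lfp, ev$peak_s, freq_range = c(5, 45),
                                window_s = 0.5, n_freq = 41,
                                align_band = c(13, 30))
write.csv(data.frame(freq_hz = sp$freq_hz,
                     t(sp$power)[seq(1, length(sp$time_s), by = 25), ]),
          file.path(out, "aligned_spectrogram_downsampled.csv"),
          row.names = FALSE)
pk <- which(sp$power == max(sp$power), arr.ind = TRUE)
message(sprintf("aligned spectrogram maximum at %.1f Hz, lag %.0f ms over %d events",
                sp$freq_hz[pk[1]], 1000 * sp$time_s[pk[2]], sp$n_events))
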