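#!/usr/bin/env Rscript
# Hybrid spontaneous-PSC detection on the simulated sEPSC recording, scored
# against the generator's ground truth. Writes the event table and a
# summary with recall/precision at +/-2 ms matching.

suppressMessages(library(striatools))
out <- "results"
tr <- read_trace(file.path(out, "sepsc_trace"))
truth <- read.csv(file.path(out, "sepsc_truth.csv"))

events <- suppressWarnings(detect_psc(tr, "sEPSC"))
write.csv(events, file.path(out, "sepsc_events.csv"), row.names = FALSE)

dur <- length(tr$samples) / tr$fs_hz
m <- match_events(events$onset_s, truth$onset_s, tol_ms = 2)
summary <- list(
  n_events = nrow(events),
  frequency_hz = event_frequency(events, dur),
  mean_amplitude_pa = mean(events$amplitude_pa),
  median_amplitude_pa = median(events$amplitude_pa),
  mean_rise_20_80_ms = mean(events$rise_20_80_ms, na.rm = TRUE),
  mean_decay_tau_ms = mean(events$decay_tau_ms, na.rm = TRUE),
  recall = m$recall, precision = m$precision
)
jsonlite::write_json(summary, file.path(out, "sepsc_summary.json"),
                     auto_unbox = TRUE, digits = NA)
message(sprintf("detected %d events (%.2f Hz); recall %.3f, precision %.3f",
                summary$n_events, summary$frequency_hz, m$recall, m$precision))
message(sprintf("mean amplitude %.1f pA, rise %.2f ms, decay tau %.1f ms",
                summary$mean_amplitude_pa, summary$mean_rise_20_80_ms,
                summary$mean_decay_tau_ms))
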