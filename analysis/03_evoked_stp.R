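#!/usr/bin/env Rscript
# Short-term-plasticity quantification of the simulated evoked train:
# per-pulse amplitudes, normalization to the first pulse, paired-pulse
# ratio and depressing/facilitating classification.

suppressMessages(library(striatools))
out <- "results"
tr <- read_trace(file.path(out, "evoked_trace"))
truth <- read.csv(file.path(out, "evoked_truth.csv"))

p <- stp_profile(tr, truth$stim_time_s, "EPSC")
tab <- data.frame(pulse = seq_along(p$raw_amplitudes_pa),
                  raw_amplitude_pa = p$raw_amplitudes_pa,
                  normalized = p$normalized_amplitudes,
                  true_normalized = truth$true_amplitude_pa /
                    truth$true_amplitude_pa[1])
write.csv(tab, file.path(out, "stp_profile.csv"), row.names = FALSE)
message(sprintf("paired-pulse ratio %.3f (true %.3f); classified %s",
                p$ppr, tab$true_normalized[2], p$classification))
message(paste(sprintf("pulse %d: %.2f", tab$pulse, tab$normalized),
              collapse = "  "))
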