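#!/usr/bin/env Rscript
# Simulate one example of each recording modality with known ground truth:
# a spontaneous EPSC trace, an evoked 20 Hz train, spike trains, unit
# waveforms and an LFP with beta bursts. Writes the ground truth tables that
# the later stages are scored against.

suppressMessages(library(striatools))
out <- "results"
dir.create(out, showWarnings = FALSE)

seed <- 1

# --- spontaneous EPSC recording (2 Hz events on a noisy drifting baseline)
psc_cfg <- psc_synth_config(duration_s = 100, event_rate_hz = 2,
                            amp_mean_pa = 25, amp_cv = 0.4, noise_sd_pa = 5,
                            drift_amp_pa = 10, seed = seed)
psc <- gen_psc_trace(psc_cfg)
write_trace(psc$trace, file.path(out, "sepsc_trace"))
write.csv(psc$truth, file.path(out, "sepsc_truth.csv"), row.names = FALSE)
message(sprintf("sEPSC trace: %d events injected over %g s",
                nrow(psc$truth), psc_cfg$duration_s))

# --- evoked 20 Hz, 8-pulse train with resource depletion
stp_cfg <- stp_synth_config(release_prob = 0.5, tau_rec_s = 0.5,
                            amp1_pa = 100, noise_sd_pa = 2, seed = seed)
ev <- gen_evoked_train(stp_cfg)
write_trace(ev$trace, file.path(out, "evoked_trace"))
write.csv(data.frame(stim_time_s = ev$stim_times_s,
                     true_amplitude_pa = ev$true_amplitudes_pa),
          file.path(out, "evoked_truth.csv"), row.names = FALSE)
message(sprintf("evoked train: true pulse-2 ratio %.3f",
                ev$true_amplitudes_pa[2] / ev$true_amplitudes_pa[1]))

# --- spike trains: one Poisson, one bursty
po <- gen_spike_train(spike_synth_config(duration_s = 600, rate_hz = 8,
                                         seed = seed))
bu <- gen_spike_train(spike_synth_config(duration_s = 600, mode = "bursty",
                                         burst_rate_hz = 1,
                                         spikes_per_burst_mean = 5,
                                         intra_burst_isi_ms = 5, seed = seed + 1))
write.csv(data.frame(unit_id = rep(c("poisson", "bursty"),
                                   c(length(po), length(bu))),
                     time_s = c(po, bu)),
          file.path(out, "spike_trains.csv"), row.names = FALSE)
message(sprintf("spike trains: %d poisson, %d bursty spikes",
                length(po), length(bu)))

# --- LFP with injected beta bursts
lfp_cfg <- lfp_synth_config(duration_s = 600,
                            burst_specs = list(burst_spec(13, 30,
                                                          rate_per_min = 10,
                                                          duration_ms_mean = 300,
                                                          amplitude_db = 8)),
                            seed = seed)
lfp <- gen_lfp(lfp_cfg)
write_trace(lfp$trace, file.path(out, "lfp_trace"))
write.csv(lfp$truth, file.path(out, "lfp_burst_truth.csv"), row.names = FALSE)
message(sprintf("LFP: %d beta bursts injected over %g s",
                nrow(lfp$truth), lfp_cfg$duration_s))
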