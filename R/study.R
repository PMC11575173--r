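#' Simulate and analyze a full lesion-vs-sham synthetic study
#'
#' End-to-end check of the pipeline: generates spontaneous EPSC/IPSC
#' recordings and evoked trains for two groups (sham, lesion) across three
#' post-lesion time windows, imposing three known contrasts --
#'
#' * increased sIPSC amplitude onto putative PV interneurons in week 3,
#' * decreased sEPSC amplitude onto D1 spiny projection neurons after
#'   week 3,
#' * enhanced short-term depression of evoked EPSCs onto PV interneurons --
#'
#' then runs the detection and measurement stages blind to the ground truth
#' and compares groups per window (Welch's t for amplitudes, two-way
#' group x pulse ANOVA for the trains).
#'
#' @param n_cells cells per group per window (default 6).
#' @param trace_duration_s spontaneous-trace length per cell (s, default 45).
#' @param effect_ipsc multiplicative lesion effect on week-3 PV-IN sIPSC
#'   amplitude (default 1.5).
#' @param effect_epsc multiplicative lesion effect on week>3 D1-SPN sEPSC
#'   amplitude (default 0.6).
#' @param lesion_release_prob evoked-train release probability in the lesion
#'   group (sham uses 0.35; higher values deplete faster, i.e. depress more).
#' @param seed RNG seed.
#' @param verbose print per-stage progress.
#' @return list with `amplitude_tests` (data.frame: measure, window,
#'   mean_sham, mean_lesion, p_value, significant, direction),
#'   `evoked_test` (comparison_result), `evoked_profiles` (list of two
#'   matrices), and `cell_table` (per-cell summary).
#' @export
run_synthetic_study <- function(n_cells = 6, trace_duration_s = 45,
                                effect_ipsc = 1.5, effect_epsc = 0.6,
                                lesion_release_prob = 0.7, seed = 1,
                                verbose = FALSE) {
  windows <- c("week2", "week3", "week_gt3")
  designs <- list(
    list(measure = "sIPSC_amplitude_PV_IN", modality = "sIPSC",
         polarity = "outward", base_amp = 30,
         effect = c(week2 = 1, week3 = effect_ipsc, week_gt3 = 1)),
    list(measure = "sEPSC_amplitude_D1_SPN", modality = "sEPSC",
         polarity = "inward", base_amp = 25,
         effect = c(week2 = 1, week3 = 1, week_gt3 = effect_epsc))
  )
  cell_rows <- list()
  amp_rows <- list()
  seed_counter <- seed * 1000L
  for (d in designs) {
    for (w in windows) {
      vals <- list(sham = numeric(0), lesion = numeric(0))
      for (g in c("sham", "lesion")) {
        mult <- if (g == "lesion") d$effect[[w]] else 1
        for (ci in seq_len(n_cells)) {
          seed_counter <- seed_counter + 1L
          cfg <- psc_synth_config(
            duration_s = trace_duration_s, fs_hz = 10000, event_rate_hz = 2,
            amp_mean_pa = d$base_amp * mult, amp_cv = 0.4,
            noise_sd_pa = d$base_amp / 6, polarity = d$polarity,
            seed = seed_counter)
          sim <- gen_psc_trace(cfg)
          ev <- detect_psc(sim$trace, modality = d$modality)
          m <- if (nrow(ev)) mean(ev$amplitude_pa) else NA_real_
          vals[[g]] <- c(vals[[g]], m)
          cell_rows[[length(cell_rows) + 1L]] <- data.frame(
            measure = d$measure, window = w, group = g, cell = ci,
            n_events = nrow(ev), mean_amplitude_pa = m,
            frequency_hz = event_frequency(ev, trace_duration_s))
        }
      }
      cmp <- compare_groups(vals$sham[!is.na(vals$sham)],
                            vals$lesion[!is.na(vals$lesion)], "welch_t")
      amp_rows[[length(amp_rows) + 1L]] <- data.frame(
        measure = d$measure, window = w,
        mean_sham = cmp$mean_a, mean_lesion = cmp$mean_b,
        p_value = cmp$p_value, significant = cmp$p_value < 0.05,
        direction = ifelse(cmp$mean_b > cmp$mean_a, "increase", "decrease"))
      if (verbose) {
        message(sprintf("%s %s: sham %.1f, lesion %.1f, p = %.3g",
                        d$measure, w, cmp$mean_a, cmp$mean_b, cmp$p_value))
      }
    }
  }
  # evoked 20 Hz trains: lesion releases more per pulse -> stronger depression
  prof <- list(sham = NULL, lesion = NULL)
  for (g in c("sham", "lesion")) {
    p0 <- if (g == "lesion") lesion_release_prob else 0.35
    rows <- t(vapply(seq_len(n_cells), function(ci) {
      seed_counter <<- seed_counter + 1L
      cfg <- stp_synth_config(release_prob = p0, tau_rec_s = 0.5,
                              amp1_pa = 100, noise_sd_pa = 2,
                              seed = seed_counter)
      sim <- gen_evoked_train(cfg)
      stp_profile(sim$trace, sim$stim_times_s, "EPSC")$normalized_amplitudes
    }, numeric(8)))
    prof[[g]] <- rows
  }
  evoked_test <- compare_groups(prof$sham, prof$lesion, "two_way_anova")
  list(amplitude_tests = do.call(rbind, amp_rows),
       evoked_test = evoked_test,
       evoked_profiles = prof,
       cell_table = do.call(rbind, cell_rows))
}
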