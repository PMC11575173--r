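#!/usr/bin/env Rscript
# End-to-end synthetic lesion-vs-sham study: three imposed contrasts
# (PV-IN sIPSC amplitude up in week 3; D1-SPN sEPSC amplitude down after
# week 3; enhanced evoked depression), analyzed blind to the ground truth.
# Takes a few minutes.

suppressMessages(library(striatools))
out <- "results"

st <- suppressWarnings(run_synthetic_study(seed = 1, verbose = TRUE))
write.csv(st$amplitude_tests, file.path(out, "study_amplitude_tests.csv"),
          row.names = FALSE)
write.csv(st$cell_table, file.path(out, "study_cells.csv"), row.names = FALSE)

message("amplitude contrasts:")
print(st$amplitude_tests, digits = 3)
message(sprintf("evoked two-way ANOVA: group p = %.3g, interaction p = %.3g",
                st$evoked_test$p_group, st$evoked_test$p_interaction))
message(sprintf("mean normalized train: sham %.3f, lesion %.3f",
                mean(st$evoked_profiles$sham), mean(st$evoked_profiles$lesion)))
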