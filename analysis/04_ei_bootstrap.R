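#!/usr/bin/env Rscript
# Bootstrap resampling of lesion-vs-sham contrasts: 75% subsamples, 1000
# iterations, percentile 95% CI and +/-3 SD noise bands; relative-change
# curves across post-lesion time windows and the E-I trajectory pairing
# the excitatory and inhibitory contrasts per window.

suppressMessages(library(striatools))
out <- "results"
seed <- 1

# synthetic per-cell amplitude data: sIPSC increase in week3, sEPSC
# decrease after week 3 (the study's imposed contrasts)
mk <- function(n, mean, s) rnorm(n, mean, s)
dat <- striatools:::with_seed(seed, list(
  epsc = list(week2 = list(sham = mk(20, 25, 3), lesion = mk(20, 25, 3)),
              week3 = list(sham = mk(20, 25, 3), lesion = mk(20, 25, 3)),
              week_gt3 = list(sham = mk(20, 25, 3), lesion = mk(20, 15, 3))),
  ipsc = list(week2 = list(sham = mk(20, 30, 4), lesion = mk(20, 30, 4)),
              week3 = list(sham = mk(20, 30, 4), lesion = mk(20, 45, 4)),
              week_gt3 = list(sham = mk(20, 30, 4), lesion = mk(20, 30, 4)))
))

cfg <- bootstrap_config(seed = seed)
for (m in names(dat)) {
  cur <- relative_change_curve(dat[[m]], cfg)
  write.csv(cur, file.path(out, sprintf("relative_change_%s.csv", m)),
            row.names = FALSE)
  message(sprintf("%s relative-change curve:", toupper(m)))
  print(cur[, c("window", "estimate", "ci_low", "ci_high", "significant")],
        digits = 3)
}

# E-I trajectory from difference-mode contrasts
diff_cfg <- bootstrap_config(mode = "difference", seed = seed + 1)
e_res <- lapply(dat$epsc, function(w) bootstrap_contrast(w$sham, w$lesion, diff_cfg))
i_res <- lapply(dat$ipsc, function(w) bootstrap_contrast(w$sham, w$lesion, diff_cfg))
traj <- ei_trajectory(e_res, i_res, cell_type = "PV_IN")
write.csv(traj, file.path(out, "ei_trajectory.csv"), row.names = FALSE)
message("E-I trajectory (delta E, delta I per window):")
print(traj, digits = 3)
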