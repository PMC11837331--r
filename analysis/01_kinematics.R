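#!/usr/bin/env Rscript
# Commanded vs realized wing kinematics for the two extreme fold
# conditions (no fold, full 100-degree fold with clap). Writes the
# kinematic time series and a summary of the realized-motion features:
# the fold phase lag and the passive wobble band of the unfolded
# handwing.

library(wingclap)
dir.create("results", showWarnings = FALSE)

summary_rows <- list()
for (theta0_deg in c(0, 100)) {
  sp <- synthetic_spec(seed = 1L, theta0 = theta0_deg * pi / 180,
                       n_cycles = 2L)
  kk <- make_kinematics(sp)
  stem <- sprintf("results/kinematics_theta%03d", theta0_deg)
  write_kinematics_csv(kk$commanded, paste0(stem, "_commanded.csv"))
  write_kinematics_csv(kk$realized, paste0(stem, "_realized.csv"))

  s <- (kk$realized$time * kk$realized$f) %% 1
  peak_cmd <- s[which.max(kk$commanded$fold)]
  peak_real <- s[which.max(kk$realized$fold)]
  summary_rows[[length(summary_rows) + 1L]] <- data.frame(
    theta0_deg = theta0_deg,
    fold_peak_commanded_tT = peak_cmd,
    fold_peak_realized_tT = peak_real,
    fold_min_deg = min(kk$realized$fold) * 180 / pi,
    fold_max_deg = max(kk$realized$fold) * 180 / pi)
}
summ <- do.call(rbind, summary_rows)
write.csv(summ, "results/kinematics_summary.csv", row.names = FALSE)
print(summ, digits = 3)
cat(sprintf(
  "\nRealized fold lags the commanded motion by %.2f cycles; the\n",
  summ$fold_peak_realized_tT[2] - summ$fold_peak_commanded_tT[2]))
cat(sprintf("unfolded handwing wobbles passively between %.0f and %.0f degrees.\n",
            summ$fold_min_deg[1], summ$fold_max_deg[1]))
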