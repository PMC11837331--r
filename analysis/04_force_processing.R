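#!/usr/bin/env Rscript
# Measurement-processing chain on synthetic transducer data: matched
# wings-on / wings-off trials (mechanism inertia + aerodynamics + noise
# vs inertia + noise), Butterworth filtering, inertia subtraction,
# normalization to CL/CP, phase averaging with the cycle-to-cycle RMS
# band, and comparison of the recovered cycle averages with the
# generator's ground truth.

library(wingclap)
dir.create("results", showWarnings = FALSE)

rows <- list()
for (theta0_deg in c(0, 60, 100)) {
  sp <- synthetic_spec(seed = 50L + theta0_deg, theta0 = theta0_deg * pi / 180,
                       n_cycles = 40L)
  tr <- make_force_traces(sp)
  net <- subtract_inertia(tr$wings_on, tr$wings_off)
  co <- normalize_trace(net, rho = 1.204, U = sp$U, S = sp$geometry$S)
  paL <- phase_average_trace(co$CL, co$time, sp$f, sp$n_bins)
  paP <- phase_average_trace(co$CP, co$time, sp$f, sp$n_bins)
  write.csv(data.frame(phase = paL$phase, CL = paL$mean, CL_sd = paL$sd,
                       CP = paP$mean, CP_sd = paP$sd),
            sprintf("results/net_coeffs_theta%03d.csv", theta0_deg),
            row.names = FALSE)
  rows[[length(rows) + 1L]] <- data.frame(
    theta0_deg = theta0_deg,
    CL_bar_recovered = mean(paL$mean), CL_bar_truth = tr$truth$CL_bar,
    CP_bar_recovered = mean(paP$mean), CP_bar_truth = tr$truth$CP_bar)
}
tab <- do.call(rbind, rows)
tab$CL_rel_err <- ifelse(abs(tab$CL_bar_truth) > 1e-6,
                         abs(tab$CL_bar_recovered - tab$CL_bar_truth) /
                           abs(tab$CL_bar_truth), NA)
write.csv(tab, "results/processing_recovery.csv", row.names = FALSE)
print(tab, row.names = FALSE, digits = 3)
cat("\nInertia subtraction recovers the aerodynamic cycle averages from\n")
cat("traces where the mechanism inertia is ~5-10x the aerodynamic signal.\n")
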