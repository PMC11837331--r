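#!/usr/bin/env Rscript
# Quasi-steady blade-element predictions: instantaneous CL(t) and CP(t)
# for the two extreme fold conditions at St = 0.21, and the
# cycle-averaged lift / power-economy surfaces over the St x theta0
# grid. The no-fold wing produces zero net lift (symmetric strokes);
# lift rises monotonically with fold amplitude. In this model power
# economy peaks at large-but-not-extreme fold (~80 degrees) and dips
# slightly at full fold: the quasi-steady model prices the extra drag
# of the clap kinematics but cannot produce the clap-jet lift that, in
# measurements, rewards full folding.

library(wingclap)
dir.create("results", showWarnings = FALSE)

g <- wing_geometry()
f <- 3; Phi <- 44 * pi / 180
A <- 2 * g$span * sin(Phi)

# instantaneous traces at U = 4 (St ~ 0.21)
U <- 4
t <- seq(0, 1 / f, length.out = 401L)[-401L]
for (theta0_deg in c(0, 100)) {
  kin <- kinematic_series(t, commanded_flap(t, f, Phi),
                          commanded_fold(t, f, theta0_deg * pi / 180),
                          f, theta0 = theta0_deg * pi / 180)
  kin <- realized_from_commanded(kin, phase_lag = 0.1, passive_wobble = FALSE)
  fp <- instantaneous_forces(element_states(kin, g, U), aero_model(U = U), g)
  write.csv(data.frame(t_over_T = t * f, CL = fp$CL, CP = fp$CP),
            sprintf("results/qs_trace_theta%03d.csv", theta0_deg),
            row.names = FALSE)
}

# cycle-averaged surfaces
St_grid <- seq(0.16, 0.41, by = 0.05)
theta0_grid <- c(0, 15, 30, 45, 60, 80, 100) * pi / 180
sw <- qs_sweep(St_grid, theta0_grid, g, f = f, flap_amplitude = Phi)
write.csv(sw, "results/cycle_summary.csv", row.names = FALSE)

cat("Cycle-averaged CL over (St, theta0):\n")
print(round(xtabs(CL_bar ~ St + theta0_deg, sw), 3))
cat("\nPower economy CL/CP:\n")
print(round(xtabs(economy ~ St + theta0_deg, sw), 3))
best <- do.call(rbind, lapply(split(sw, sw$St), function(d)
  d[which.max(d$economy), c("St", "theta0_deg", "economy")]))
cat("\nMost economical fold amplitude per St:\n")
print(best, row.names = FALSE, digits = 3)
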