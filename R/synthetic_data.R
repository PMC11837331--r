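#' Specification for the synthetic study conditions
#'
#' Bundles the parameters of the emulated experiment: geometry, flapping
#' conditions, realized-kinematics imperfections, mechanism-inertia
#' harmonics, noise levels and the clap-jet shape. Defaults mirror the
#' study conditions of the physical platform: 3 Hz flapping at U = 4
#' m/s, 40 cycles per trial, force channel at 1000 Hz, motor channel at
#' 512 Hz, velocimetry at 500 Hz, 83 phase bins. All generators driven by
#' a `synthetic_spec` are pure functions of (spec, seed).
#'
#' The clap jet is Gaussian in space (core radius `sigma_j`) and a
#' raised-cosine pulse in phase centred at the clap (t/T = 0.8), tilted
#' rear-down by `tilt` from vertical; its peak speed scales with the
#' handwing closing-speed scale, \eqn{V_j = k_j f \theta_o b}. An
#' optional weaker upward "scooping" lobe precedes the clap, reproducing
#' the negative lift trough seen as the wingtips approach each other.
#'
#' @param seed integer seed; identical spec + seed gives identical output.
#' @param geometry a [wing_geometry()].
#' @param f flapping frequency, Hz.
#' @param U freestream speed, m s^-1.
#' @param theta0 fold amplitude, rad.
#' @param flap_amplitude flap half-amplitude, rad.
#' @param phase_lag realized fold phase lag, cycles.
#' @param n_cycles cycles per trial.
#' @param force_rate,power_rate,field_rate channel sample rates, Hz.
#' @param n_bins phase bins per cycle.
#' @param noise_force force-channel noise SD, N.
#' @param noise_power power-channel noise SD, W.
#' @param noise_velocity velocity noise SD, m s^-1.
#' @param inertia list: `A1`, `A2` force harmonic amplitudes (N) at f and
#'   2f with phases `ph1`, `ph2`; `P1`, `P2` power harmonics (W).
#' @param jet list: `k_j` peak-speed coefficient (V_j = k_j f theta0 b),
#'   `sigma` core radius (m), `x0`, `z0` centre (m), `phase0` pulse
#'   centre (cycle fraction), `width` pulse half-width (cycle fraction),
#'   `tilt` rear-down tilt from vertical (rad), `scoop` relative
#'   amplitude of the upward pre-clap lobe (0 disables), `scoop_phase`
#'   its centre.
#' @param trigger_offset hardware-trigger phase offset between wings-on
#'   and wings-off trials, cycles.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L, geometry = wing_geometry(),
                           f = 3, U = 4, theta0 = 100 * pi / 180,
                           flap_amplitude = 44 * pi / 180,
                           phase_lag = 0.1, n_cycles = 40L,
                           force_rate = 1000, power_rate = 512,
                           field_rate = 500, n_bins = 83L,
                           noise_force = 0.02, noise_power = 0.2,
                           noise_velocity = 0.05,
                           inertia = list(A1 = 2, A2 = 0.5,
                                          ph1 = 0.4, ph2 = 1.1,
                                          P1 = 5, P2 = 2),
                           jet = list(k_j = 7.5, sigma = 0.03,
                                      x0 = 0, z0 = 0,
                                      phase0 = 0.8, width = 0.15,
                                      tilt = 20 * pi / 180,
                                      scoop = 0.35, scoop_phase = 0.62),
                           trigger_offset = 0) {
  stopifnot(inherits(geometry, "wing_geometry"), f > 0, U > 0, theta0 >= 0,
            n_cycles >= 1, jet$sigma > 0)
  structure(as.list(environment()), class = "synthetic_spec")
}

#' Generate commanded and realized kinematics
#'
#' Commanded flap/fold series on the force-channel clock, plus the
#' realized series with the fold phase lag and (in the no-fold condition)
#' the passive handwing wobble.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `commanded` and `realized` [kinematic_series()].
#' @export
make_kinematics <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- round(spec$n_cycles * spec$force_rate / spec$f)
  time <- (seq_len(n) - 1L) / spec$force_rate
  cmd <- kinematic_series(time,
                          commanded_flap(time, spec$f, spec$flap_amplitude),
                          commanded_fold(time, spec$f, spec$theta0),
                          spec$f, theta0 = spec$theta0)
  list(commanded = cmd,
       realized = realized_from_commanded(cmd, spec$phase_lag))
}

# One cycle of realized kinematics on an exact-cycle clock (the force
# clock does not divide the period evenly; downstream sampling is
# phase-periodic anyway).
one_cycle_realized <- function(spec, n_per_cycle = 400L) {
  t1 <- seq(0, 1 / spec$f, length.out = n_per_cycle + 1L)[-(n_per_cycle + 1L)]
  cmd <- kinematic_series(t1,
                          commanded_flap(t1, spec$f, spec$flap_amplitude),
                          commanded_fold(t1, spec$f, spec$theta0),
                          spec$f, theta0 = spec$theta0)
  realized_from_commanded(cmd, spec$phase_lag)
}

# Phase-periodic resampling of a one-cycle coefficient series onto an
# arbitrary clock.
resample_cycle <- function(fps, f, tout) {
  ph <- (fps$time * f) %% 1
  list(CL = interp_periodic(ph, fps$CL, tout * f),
       CP = interp_periodic(ph, fps$CP, tout * f))
}

#' Generate matched wings-on / wings-off force and power traces
#'
#' Emulates the measurement protocol: the wings-on trial is the sum of a
#' mechanism-inertia component (harmonics at f and 2f), the denormalized
#' aerodynamic truth, and Gaussian noise; the wings-off trial repeats the
#' same inertia with independent noise. The aerodynamic ground truth is
#' attached so recovery by [subtract_inertia()] + [normalize_trace()] can
#' be checked.
#'
#' @param spec a [synthetic_spec()].
#' @param aero_truth a `force_power_series` covering one or more cycles
#'   (e.g. from [instantaneous_forces()] on the realized kinematics). If
#'   NULL, it is computed from the spec via the quasi-steady model.
#' @return list with `wings_on`, `wings_off` ([force_trace()] objects)
#'   and `truth` (list: `CL`, `CP` on the force clock, `CL_bar`,
#'   `CP_bar`).
#' @export
make_force_traces <- function(spec, aero_truth = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(aero_truth)) {
    k1 <- one_cycle_realized(spec)
    st <- element_states(k1, spec$geometry, spec$U)
    aero_truth <- instantaneous_forces(
      st, aero_model(rho = spec$geometry$air_density, U = spec$U), spec$geometry)
  }
  nf <- round(spec$n_cycles * spec$force_rate / spec$f)
  np <- round(spec$n_cycles * spec$power_rate / spec$f)
  tf <- (seq_len(nf) - 1L) / spec$force_rate
  tp <- (seq_len(np) - 1L) / spec$power_rate
  q <- 0.5 * spec$geometry$air_density * spec$U^2
  S <- spec$geometry$S
  cyF <- resample_cycle(aero_truth, spec$f, tf)
  cyP <- resample_cycle(aero_truth, spec$f, tp)
  Fz_aero <- cyF$CL * q * S
  P_aero <- cyP$CP * q * spec$U * S
  inertia_F <- function(t, dphase = 0) {
    w <- 2 * pi * spec$f
    spec$inertia$A1 * cos(w * t + spec$inertia$ph1 + 2 * pi * dphase) +
      spec$inertia$A2 * cos(2 * w * t + spec$inertia$ph2 + 4 * pi * dphase)
  }
  inertia_P <- function(t, dphase = 0) {
    w <- 2 * pi * spec$f
    spec$inertia$P1 * cos(w * t + spec$inertia$ph1 + 0.7 + 2 * pi * dphase) +
      spec$inertia$P2 * cos(2 * w * t + spec$inertia$ph2 + 0.3 + 4 * pi * dphase)
  }
  d <- spec$trigger_offset
  with_seed(spec$seed, {
    on <- force_trace(tf, inertia_F(tf) + Fz_aero + stats::rnorm(nf, 0, spec$noise_force),
                      tp, inertia_P(tp) + P_aero + stats::rnorm(np, 0, spec$noise_power),
                      "wings_on", spec$f, spec$theta0, spec$U)
    off <- force_trace(tf, inertia_F(tf, d) + stats::rnorm(nf, 0, spec$noise_force),
                       tp, inertia_P(tp, d) + stats::rnorm(np, 0, spec$noise_power),
                       "wings_off", spec$f, spec$theta0, spec$U)
    list(wings_on = on, wings_off = off,
         truth = list(CL = cyF$CL, CP = cyF$CP,
                      CL_bar = mean(cyF$CL), CP_bar = mean(cyF$CP)))
  })
}

# Analytic (noise-free) jet velocity field of a spec, vectorized over a
# grid: returns u and w (z, x) at one cycle fraction s.
jet_field_at <- function(spec, s, x, z) {
  jt <- spec$jet
  Vj <- jt$k_j * spec$f * spec$theta0 * spec$geometry$handwing_length
  pulse <- function(s, s0, hw) {
    d <- (s - s0) %% 1; d <- pmin(d, 1 - d)
    ifelse(d < hw, 0.5 * (1 + cos(pi * d / hw)), 0)
  }
  G <- exp(-(outer(
    (z - jt$z0)^2, (x - jt$x0)^2, "+")) / (2 * jt$sigma^2))
  g <- pulse(s, jt$phase0, jt$width)
  gs <- if (jt$scoop > 0) pulse(s, jt$scoop_phase, jt$width) else 0
  list(u = spec$U + Vj * sin(jt$tilt) * g * G,
       w = -Vj * cos(jt$tilt) * g * G + jt$scoop * Vj * gs * G)
}

#' Generate a raw clap-jet snapshot series with analytic ground truth
#'
#' Emulates the planar velocimetry measurement: snapshots at the field
#' sample rate over `n_cycles` cycles of a uniform freestream plus a
#' transient, downward, rear-tilted Gaussian clap jet (and an optional
#' upward pre-clap "scooping" lobe), with Gaussian velocity noise. The
#' generator's own force budget — the same three control-volume terms,
#' evaluated from the analytic field with analytic phase derivatives on a
#' refined grid — is returned as ground truth.
#'
#' @param spec a [synthetic_spec()].
#' @param x,z grid coordinates, m (defaults: 600 x 400 mm field of view
#'   at 10 mm pitch). The jet core must lie inside the domain.
#' @return list with `snapshots` (list `x`, `z`, `times`, `u`, `w`,
#'   `U`, `f`, `rho`) and `truth_fun`: function(cv, n_phase, refine)
#'   returning the analytic per-phase budget (data.frame like a
#'   `force_budget`).
#' @export
make_jet_fields <- function(spec,
                            x = seq(-0.3, 0.3, by = 0.01),
                            z = seq(-0.2, 0.2, by = 0.01)) {
  stopifnot(inherits(spec, "synthetic_spec"))
  jt <- spec$jet
  if (jt$x0 - 3 * jt$sigma < min(x) || jt$x0 + 3 * jt$sigma > max(x) ||
      jt$z0 - 3 * jt$sigma < min(z) || jt$z0 + 3 * jt$sigma > max(z))
    stop("jet core (3 sigma) overlaps the field domain boundary")
  n <- round(spec$n_cycles * spec$field_rate / spec$f)
  times <- (seq_len(n) - 1L) / spec$field_rate
  nz <- length(z); nx <- length(x)
  u <- w <- array(0, c(n, nz, nx))
  for (i in seq_len(n)) {
    fl <- jet_field_at(spec, (times[i] * spec$f) %% 1, x, z)
    u[i, , ] <- fl$u
    w[i, , ] <- fl$w
  }
  snaps <- with_seed(spec$seed + 1L, {
    if (spec$noise_velocity > 0) {
      u <- u + array(stats::rnorm(length(u), 0, spec$noise_velocity), dim(u))
      w <- w + array(stats::rnorm(length(w), 0, spec$noise_velocity), dim(w))
    }
    list(x = x, z = z, times = times, u = u, w = w,
         U = spec$U, f = spec$f, rho = spec$geometry$air_density)
  })
  list(snapshots = snaps,
       truth_fun = function(cv, n_phase = 10L * spec$n_bins, refine = 4L)
         jet_truth_budget(spec, cv, n_phase = n_phase, refine = refine))
}

#' Analytic control-volume budget of the synthetic jet
#'
#' Evaluates the three-term lift budget of the prescribed (noise-free)
#' jet field on a `refine`-times finer spatial grid and `n_phase` phase
#' stations, using dense central differences in phase. This is the
#' generator's own ground truth for the discrete pipeline.
#'
#' @param spec a [synthetic_spec()].
#' @param cv a [cv_spec()].
#' @param n_phase number of phase stations (default 830).
#' @param refine spatial refinement factor relative to 10 mm pitch.
#' @return data.frame `phase`, `accel`, `momentum`, `pressure`, `total`,
#'   `force`, `CL` (a `force_budget`).
#' @export
jet_truth_budget <- function(spec, cv, n_phase = 830L, refine = 4L) {
  dxf <- 0.01 / refine
  xf <- seq(cv$x_min, cv$x_max, by = dxf)
  zf <- seq(cv$z_min, cv$z_max, by = dxf)
  ph <- (seq_len(n_phase) - 0.5) / n_phase
  rho <- spec$geometry$air_density
  ds <- 1 / n_phase
  eps <- ds / 10                       # dense central phase differences
  nz <- length(zf); nx <- length(xf)
  u <- w <- dudt <- dwdt <- array(0, c(n_phase, nz, nx))
  for (b in seq_len(n_phase)) {
    fl <- jet_field_at(spec, ph[b], xf, zf)
    fp <- jet_field_at(spec, ph[b] + eps, xf, zf)
    fm <- jet_field_at(spec, ph[b] - eps, xf, zf)
    u[b, , ] <- fl$u; w[b, , ] <- fl$w
    dudt[b, , ] <- (fp$u - fm$u) / (2 * eps) * spec$f
    dwdt[b, , ] <- (fp$w - fm$w) / (2 * eps) * spec$f
  }
  accel <- vapply(seq_len(n_phase), function(b)
    rho * trapz2d(-dwdt[b, , ], zf, xf), numeric(1))
  mom <- vapply(seq_len(n_phase), function(b) {
    wd <- -w[b, , ]
    rho * (trapz1d(wd[, nx] * u[b, , nx], zf) -
           trapz1d(wd[, 1L] * u[b, , 1L], zf) +
           trapz1d(wd[nz, ] * w[b, nz, ], xf) -
           trapz1d(wd[1L, ] * w[b, 1L, ], xf))
  }, numeric(1))
  edge_p <- function(b, irow) {
    # inviscid streamwise momentum integration with analytic derivatives
    ub <- u[b, , ]
    dudx <- c((ub[irow, 2L] - ub[irow, 1L]) / dxf,
              (ub[irow, -(1:2)] - ub[irow, -((nx - 1):nx)]) / (2 * dxf),
              (ub[irow, nx] - ub[irow, nx - 1L]) / dxf)
    jm <- max(1L, irow - 1L); jp <- min(nz, irow + 1L)
    dudz <- (ub[jp, ] - ub[jm, ]) / ((jp - jm) * dxf)
    dpdx <- -rho * (dudt[b, irow, ] + ub[irow, ] * dudx + w[b, irow, ] * dudz)
    cumtrapz1d(dpdx, xf)
  }
  prs <- vapply(seq_len(n_phase), function(b)
    trapz1d(edge_p(b, 1L) - edge_p(b, nz), xf), numeric(1))
  tot <- accel + mom + prs
  q <- 0.5 * rho * spec$U^2
  structure(data.frame(phase = ph, accel = accel, momentum = mom,
                       pressure = prs, total = tot,
                       force = tot * cv$jet_width,
                       CL = tot / (q * cv$chord)),
            class = c("force_budget", "data.frame"),
            cv = cv, U = spec$U, f = spec$f, rho = rho,
            method = "analytic")
}
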