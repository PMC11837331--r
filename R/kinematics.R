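#' Kinematic series for a flapping-folding wing
#'
#' Container for the two wing degrees of freedom over time: the flapping
#' angle \eqn{\phi} of the armwing relative to horizontal, and the folding
#' angle \eqn{\theta} of the handwing relative to the armwing (positive
#' folds the handwing ventrally, toward the clap). Time is uniform and the
#' phase origin t/T = 0 is the top of the downstroke (dorsal extreme).
#'
#' @param time time stamps, s, uniform grid covering >= 1 cycle.
#' @param flap flapping angle \eqn{\phi(t)}, rad.
#' @param fold folding angle \eqn{\theta(t)}, rad.
#' @param f flapping frequency, Hz.
#' @param theta0 commanded fold amplitude \eqn{\theta_o}, rad (condition label).
#' @param fold_onset cycle fraction at which folding starts (default 1/3).
#' @return object of class `kinematic_series`.
#' @export
kinematic_series <- function(time, flap, fold, f, theta0 = max(fold),
                             fold_onset = 1/3) {
  dt <- check_uniform_time(time)
  if (length(flap) != length(time) || length(fold) != length(time))
    stop("flap and fold must have the same length as time")
  if (!isTRUE(f > 0)) stop("frequency must be positive")
  if ((time[length(time)] - time[1L] + dt) * f < 1 - 1e-9)
    stop("series must cover at least one flapping cycle")
  structure(list(time = time, flap = flap, fold = fold,
                 f = f, period = 1 / f, theta0 = theta0,
                 fold_onset = fold_onset, dt = dt),
            class = "kinematic_series")
}

#' @export
print.kinematic_series <- function(x, ...) {
  cat(sprintf("Kinematic series: %d samples at %.0f Hz, f = %g Hz (%.2f cycles)\n",
              length(x$time), 1 / x$dt, x$f,
              (x$time[length(x$time)] - x$time[1L] + x$dt) * x$f))
  cat(sprintf("  flap in [%.1f, %.1f] deg, fold in [%.1f, %.1f] deg (theta0 = %.1f deg)\n",
              min(x$flap) * 180 / pi, max(x$flap) * 180 / pi,
              min(x$fold) * 180 / pi, max(x$fold) * 180 / pi,
              x$theta0 * 180 / pi))
  invisible(x)
}

#' Commanded flapping-angle series
#'
#' The flap drive rotates a crank at constant speed; the armwing (rocker)
#' oscillates. `mode = "sinusoid"` is the idealized drive
#' \eqn{\phi(t) = \Phi \cos(2\pi f t)}; `mode = "fourbar"` solves the
#' crank-rocker linkage at constant crank speed and centres (and, when
#' `amplitude` is given, rescales) the rocker oscillation. In both modes
#' t = 0 is the dorsal extreme, so the first half-cycle is the downstroke.
#'
#' @param time time stamps, s (uniform).
#' @param f flapping frequency, Hz (> 0).
#' @param amplitude rocker half-amplitude \eqn{\Phi}, rad. Default 44
#'   degrees, which gives a no-fold wingtip excursion A = 2 R sin(Phi)
#'   of about 0.28 m for the default geometry.
#' @param mode `"sinusoid"` (default) or `"fourbar"`.
#' @param links four-bar link lengths (see [fourbar_rocker_angle()]),
#'   required for `mode = "fourbar"`.
#' @return flap angle series, rad.
#' @export
commanded_flap <- function(time, f, amplitude = 44 * pi / 180,
                           mode = c("sinusoid", "fourbar"), links = NULL) {
  mode <- match.arg(mode)
  if (!isTRUE(f > 0)) stop("frequency must be positive (got f = ", f, ")")
  if (mode == "sinusoid") {
    amplitude * cos(2 * pi * f * time)
  } else {
    if (is.null(links)) stop("fourbar mode needs link lengths")
    tog <- fourbar_toggle_angles(links)
    # crank phase with the rocker at its dorsal extreme at t = 0:
    # locate the crank angle of maximum rocker angle on a dense grid,
    # refined by golden-section search.
    grid <- seq(0, 2 * pi, length.out = 2048L)
    rg <- fourbar_rocker_angle(grid, links)
    b0 <- grid[which.max(rg)]
    opt <- stats::optimize(function(b) -fourbar_rocker_angle(b, links),
                           interval = b0 + c(-0.01, 0.01) * 2 * pi)
    b0 <- opt$minimum
    phi <- fourbar_rocker_angle(b0 + 2 * pi * f * time, links)
    phi <- phi - mean(tog)                 # centre on the stroke midline
    if (!is.null(amplitude)) {
      half <- (tog[["max"]] - tog[["min"]]) / 2
      phi <- phi * amplitude / half        # requested rocker half-amplitude
    }
    phi
  }
}

#' Commanded folding-angle series
#'
#' The fold drive is idle for the first `fold_onset` fraction of each cycle
#' (default 1/3, late downstroke) and then executes one smooth sinusoidal
#' fold-and-return pulse that ends with the cycle:
#' \deqn{\theta = (\theta_o/2)\,[1 - \cos(2\pi (s - s_0)/(1 - s_0))]}
#' for cycle fraction \eqn{s \ge s_0}. The pulse peaks at \eqn{\theta_o}
#' (at s = 2/3 for the default onset) and is C1-continuous at onset and
#' cycle end.
#'
#' @inheritParams commanded_flap
#' @param theta0 fold amplitude \eqn{\theta_o}, rad (>= 0).
#' @param fold_onset cycle fraction in [0, 1) at which folding starts.
#' @return fold angle series, rad.
#' @export
commanded_fold <- function(time, f, theta0, fold_onset = 1/3) {
  if (!isTRUE(f > 0)) stop("frequency must be positive")
  if (theta0 < 0) stop("fold amplitude theta0 must be >= 0 (got ", theta0, ")")
  if (fold_onset < 0 || fold_onset >= 1) stop("fold_onset must be in [0, 1)")
  s <- (time * f) %% 1
  th <- ifelse(s < fold_onset, 0,
               (theta0 / 2) * (1 - cos(2 * pi * (s - fold_onset) / (1 - fold_onset))))
  th
}

#' Realized kinematics from commanded kinematics
#'
#' Emulates the realized motion of the physical drive: the flap follows
#' the commanded motion, while the fold lags it by `phase_lag` cycles
#' (about 0.1 in practice). In the no-fold condition the handwing is not
#' rigidly held and oscillates passively within a small band (default
#' -20 to +5 degrees).
#'
#' @param kin a commanded [kinematic_series()].
#' @param phase_lag fold phase lag, cycle fraction in [0, 0.25].
#' @param passive_wobble add the passive no-fold oscillation when
#'   `theta0 == 0`?
#' @param wobble_band numeric length 2, rad: bounds of the passive
#'   oscillation.
#' @return a realized `kinematic_series`.
#' @export
realized_from_commanded <- function(kin, phase_lag = 0.1,
                                    passive_wobble = TRUE,
                                    wobble_band = c(-20, 5) * pi / 180) {
  stopifnot(inherits(kin, "kinematic_series"))
  if (phase_lag < 0 || phase_lag > 0.25)
    stop("phase_lag must be in [0, 0.25]")
  s <- (kin$time * kin$f) %% 1
  if (kin$theta0 == 0 && passive_wobble) {
    mid <- mean(wobble_band); amp <- diff(wobble_band) / 2
    fold <- mid + amp * cos(2 * pi * (s - 0.55))
  } else {
    # delay by phase_lag cycles, wrapping (commanded fold is periodic)
    fold <- commanded_fold((s - phase_lag) / kin$f, kin$f,
                           kin$theta0, kin$fold_onset)
  }
  kinematic_series(kin$time, kin$flap, fold, kin$f,
                   theta0 = kin$theta0, fold_onset = kin$fold_onset)
}

#' Per-element positions, velocities and effective angles of attack
#'
#' Resolves the wing into spanwise blade elements and computes, for every
#' time step, the element's vertical position and velocity, the velocity
#' component normal to the wing surface, the effective velocity seen by
#' the element (freestream plus motion-induced), and the effective angle
#' of attack (eAoA). Armwing elements ride on the flap alone; handwing
#' elements additionally rotate with the fold, with surface orientation
#' \eqn{\psi = \phi - \theta} (positive fold is ventral). Angular rates
#' come from Savitzky-Golay differentiation (order 2, frame 5) of the
#' sampled angle series.
#'
#' Because folding (like flapping) rotates the wing about a *chordwise*
#' axis, the section's incidence is set by the velocity component normal
#' to its own surface, not by the vertical velocity alone: for an armwing
#' element \eqn{v_n = r\dot\phi}, for a handwing element
#' \eqn{v_n = L_a\dot\phi\cos\theta + (r - L_a)\dot\psi}. The eAoA is
#' \eqn{\alpha = \mathrm{atan2}(-v_n, U)}: an element sweeping toward its
#' ventral side (downward for an unfolded wing) sees positive incidence.
#' The vertical position `z` and velocity `w` (chain-rule derivative of
#' z) are also reported; for an unfolded wing at mid-stroke they coincide
#' with the normal-velocity description.
#'
#' @param kin a [kinematic_series()].
#' @param geometry a [wing_geometry()].
#' @param U freestream speed, m s^-1 (> 0).
#' @param periodic treat the angle series as periodic when
#'   differentiating? Default: auto-detect a whole number of cycles
#'   (commanded motion is exactly cyclic; the wrap-around stencil then
#'   preserves the stroke symmetries that one-sided end stencils break).
#' @return object of class `element_states`: list with element vectors
#'   `r`, `dr`, `is_handwing` and time-by-element matrices `z`, `w`,
#'   `v_n`, `orient` (surface orientation angle from horizontal),
#'   `U_eff`, `alpha_eff`, plus `time`, `U`, and the generating inputs.
#' @export
element_states <- function(kin, geometry, U, periodic = NULL) {
  stopifnot(inherits(kin, "kinematic_series"), inherits(geometry, "wing_geometry"))
  if (!isTRUE(U > 0)) stop("freestream U must be positive")
  if (length(kin$time) < SG_FRAME)
    stop("need at least ", SG_FRAME, " samples to differentiate the kinematics")
  if (is.null(periodic)) {
    span <- length(kin$time) * kin$dt * kin$f
    periodic <- abs(span - round(span)) < 1e-9
  }
  eg <- element_grid(geometry)
  La <- geometry$armwing_length
  phi <- kin$flap; theta <- kin$fold
  dphi <- sg_derivative(phi, kin$dt, periodic = periodic)
  dtheta <- sg_derivative(theta, kin$dt, periodic = periodic)
  psi <- phi - theta
  dpsi <- dphi - dtheta

  nt <- length(kin$time); ne <- length(eg$r)
  z <- w <- vn <- orient <- matrix(0, nt, ne)
  for (j in seq_len(ne)) {
    r <- eg$r[j]
    if (!eg$is_handwing[j]) {
      z[, j] <- r * sin(phi)
      w[, j] <- r * dphi * cos(phi)
      vn[, j] <- r * dphi
      orient[, j] <- phi
    } else {
      z[, j] <- La * sin(phi) + (r - La) * sin(psi)
      w[, j] <- La * dphi * cos(phi) + (r - La) * dpsi * cos(psi)
      vn[, j] <- La * dphi * cos(theta) + (r - La) * dpsi
      orient[, j] <- psi
    }
  }
  structure(list(time = kin$time, dt = kin$dt, f = kin$f, U = U,
                 r = eg$r, dr = eg$dr, is_handwing = eg$is_handwing,
                 z = z, w = w, v_n = vn, orient = orient,
                 U_eff = sqrt(U^2 + vn^2),
                 alpha_eff = atan2(-vn, U),
                 kin = kin, geometry = geometry),
            class = "element_states")
}
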