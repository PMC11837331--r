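#' Quasi-steady aerodynamic model
#'
#' Translational force-coefficient law and air properties for the
#' blade-element quasi-steady model. The generalized flat-plate law
#' \deqn{C_L(\alpha) = A_L \sin 2\alpha, \quad
#'       C_D(\alpha) = C_{D0} + A_D (1 - \cos 2\alpha)}
#' captures lift up to the high effective angles of attack reached by
#' revolving/flapping wings with an attached leading-edge vortex. It
#' cannot represent LEV shedding, wake capture or wing-wing interaction.
#'
#' @param A_L lift-law amplitude (dimensionless), default 1.7.
#' @param C_D0 profile drag coefficient at zero incidence, default 0.05.
#' @param A_D drag-law amplitude, default 1.7.
#' @param rho air density, kg m^-3.
#' @param U freestream speed, m s^-1.
#' @return object of class `aero_model` with the parameters plus the
#'   freestream dynamic pressure `q` = 1/2 rho U^2 (Pa).
#' @export
aero_model <- function(A_L = 1.7, C_D0 = 0.05, A_D = 1.7,
                       rho = 1.204, U = 4) {
  stopifnot(rho > 0, U > 0, C_D0 >= 0, A_D >= 0)
  structure(list(A_L = A_L, C_D0 = C_D0, A_D = A_D, rho = rho, U = U,
                 q = 0.5 * rho * U^2),
            class = "aero_model")
}

#' Blade-element force coefficients
#'
#' @param alpha effective angle of attack, rad (|alpha| <= pi/2).
#' @param model an [aero_model()].
#' @return list with `C_L` (odd in alpha) and `C_D` (even in alpha,
#'   >= C_D0).
#' @export
element_coefficients <- function(alpha, model = aero_model()) {
  if (any(abs(alpha) > pi / 2 + 1e-12))
    stop("effective angle of attack outside [-pi/2, pi/2]")
  list(C_L = model$A_L * sin(2 * alpha),
       C_D = model$C_D0 + model$A_D * (1 - cos(2 * alpha)))
}

#' Instantaneous lift and power from blade elements
#'
#' Quasi-steady force assembly: each element sees dynamic pressure
#' \eqn{q_{eff} = \rho U_{eff}^2 / 2} and produces lift
#' \eqn{dL = q_{eff}\, c\, dr\, C_L(\alpha)} perpendicular to, and drag
#' \eqn{dD = q_{eff}\, c\, dr\, C_D(\alpha)} parallel to, its relative
#' wind, which lies in the plane spanned by the freestream and the
#' element's surface normal. The resulting surface-normal force is
#' projected onto the vertical by the element's orientation (cos phi for
#' armwing, cos psi for handwing elements — a near-vertical folded
#' handwing "slices" and contributes little lift), then summed over
#' elements and mirrored over both half-wings to give \eqn{F_z(t)}.
#' Aerodynamic power is the rate of work done by the wing on the air,
#' \eqn{P = \sum dD\, U_{eff}} (lift is perpendicular to the relative
#' wind and does no work in that frame). Coefficients use the freestream
#' dynamic pressure and the reference area: \eqn{C_L = F_z / (q S)},
#' \eqn{C_P = P / (q U S)}.
#'
#' @param states an [element_states()] series (one half-wing; the mirror
#'   wing is assumed symmetric).
#' @param model an [aero_model()].
#' @param geometry the [wing_geometry()] used to build `states`.
#' @return object of class `force_power_series`: data.frame with columns
#'   `time`, `CL`, `CP`, `Fz`, `P`; attributes `f`, `model`, `geometry`.
#' @export
instantaneous_forces <- function(states, model = aero_model(U = states$U),
                                 geometry = states$geometry) {
  stopifnot(inherits(states, "element_states"))
  if (!identical(dim(states$w), c(length(states$time), length(states$r))))
    stop("element state matrices do not match the time/element grids")
  if (abs(model$U - states$U) > 1e-12)
    stop("aero model freestream differs from the one used for element states")
  co <- element_coefficients(states$alpha_eff, model)
  q_eff <- 0.5 * model$rho * states$U_eff^2
  area <- matrix(geometry$chord * states$dr, nrow = length(states$time),
                 ncol = length(states$r), byrow = TRUE)
  dL <- q_eff * area * co$C_L
  dD <- q_eff * area * co$C_D
  lam <- states$alpha_eff            # flow angle of the relative wind
  # surface-normal component of lift + drag, projected onto vertical
  dFz <- (dL * cos(lam) + dD * sin(lam)) * cos(states$orient)
  Fz <- 2 * rowSums(dFz)             # both half-wings
  P <- 2 * rowSums(dD * states$U_eff)
  S <- geometry$S
  out <- data.frame(time = states$time,
                    CL = Fz / (model$q * S),
                    CP = P / (model$q * model$U * S),
                    Fz = Fz, P = P)
  structure(out, class = c("force_power_series", "data.frame"),
            f = states$f, model = model, geometry = geometry, U = model$U)
}

#' Cycle averages of lift, power and power economy
#'
#' Time-mean of the lift and power coefficients over an integer number of
#' flapping cycles, and the power economy CL/CP.
#'
#' @param fps a `force_power_series` (or any data.frame with `time`,
#'   `CL`, `CP`) covering a whole number of cycles.
#' @param f flapping frequency, Hz; taken from the series attribute if
#'   present.
#' @return list with `CL_bar`, `CP_bar` and `economy` (NA with a warning
#'   when `CP_bar` is 0).
#' @export
cycle_average <- function(fps, f = attr(fps, "f")) {
  if (is.null(f)) stop("flapping frequency not supplied")
  dt <- check_uniform_time(fps$time)
  span <- length(fps$time) * dt
  n_cycles <- span * f
  if (abs(n_cycles - round(n_cycles)) > 1e-6)
    stop("series spans ", signif(n_cycles, 6),
         " cycles; cycle averages need an integer number of cycles")
  CL_bar <- mean(fps$CL)
  CP_bar <- mean(fps$CP)
  economy <- if (CP_bar == 0) {
    warning("CP_bar is zero; power economy undefined")
    NA_real_
  } else CL_bar / CP_bar
  list(CL_bar = CL_bar, CP_bar = CP_bar, economy = economy)
}

#' Sweep cycle-averaged performance over Strouhal number and fold amplitude
#'
#' Runs the quasi-steady chain (commanded or realized kinematics ->
#' element states -> forces -> cycle averages) on a grid of Strouhal
#' numbers and fold amplitudes. St is realized by varying the freestream
#' U at fixed flapping frequency and tip excursion: U = f A / St with
#' A = 2 R sin(Phi) the no-fold peak-to-peak tip excursion.
#'
#' @param St_grid Strouhal numbers (> 0).
#' @param theta0_grid fold amplitudes, rad.
#' @param geometry a [wing_geometry()].
#' @param f flapping frequency, Hz.
#' @param flap_amplitude flap half-amplitude Phi, rad.
#' @param fold_onset cycle fraction at which folding starts.
#' @param realized use realized (lagged) rather than commanded fold?
#' @param phase_lag fold phase lag when `realized = TRUE`.
#' @param A_L,C_D0,A_D coefficient-law constants, see [aero_model()].
#' @param rho air density, kg m^-3.
#' @param n_per_cycle kinematic samples per cycle.
#' @return data.frame (one row per grid point): `St`, `theta0_deg`,
#'   `CL_bar`, `CP_bar`, `economy`, `U`, `f`, `A`.
#' @export
qs_sweep <- function(St_grid, theta0_grid, geometry = wing_geometry(),
                     f = 3, flap_amplitude = 44 * pi / 180,
                     fold_onset = 1/3, realized = FALSE, phase_lag = 0.1,
                     A_L = 1.7, C_D0 = 0.05, A_D = 1.7, rho = 1.204,
                     n_per_cycle = 400L) {
  if (!length(St_grid) || !length(theta0_grid)) stop("grids must be non-empty")
  if (any(St_grid <= 0)) stop("St must be positive")
  A <- 2 * geometry$span * sin(flap_amplitude)
  time <- seq(0, 1 / f, length.out = n_per_cycle + 1L)[-(n_per_cycle + 1L)]
  grid <- expand.grid(theta0 = theta0_grid, St = St_grid)[, c("St", "theta0")]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    St <- grid$St[i]; th0 <- grid$theta0[i]
    U <- f * A / St
    kin <- kinematic_series(time,
                            commanded_flap(time, f, flap_amplitude),
                            commanded_fold(time, f, th0, fold_onset),
                            f, theta0 = th0, fold_onset = fold_onset)
    if (realized)
      kin <- realized_from_commanded(kin, phase_lag, passive_wobble = FALSE)
    st <- element_states(kin, geometry, U)
    fp <- instantaneous_forces(st, aero_model(A_L, C_D0, A_D, rho, U), geometry)
    cy <- cycle_average(fp)
    data.frame(St = St, theta0_deg = th0 * 180 / pi,
               CL_bar = cy$CL_bar, CP_bar = cy$CP_bar,
               economy = cy$economy, U = U, f = f, A = A)
  })
  do.call(rbind, rows)
}
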