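#' Phase-resolved planar velocity-field series
#'
#' Container for phase-averaged planar (x-z) velocity fields on a regular
#' grid, as produced by time-resolved planar velocimetry binned over the
#' flapping cycle. Arrays are shaped (phase, z, x); phase bins cover
#' exactly one cycle, bin b holding fractional phases in
#' [(b-1)/n, b/n). x points downstream, z up.
#'
#' @param x,z grid coordinates, m, strictly increasing and uniform.
#' @param u,w velocity arrays (phase, z, x), m s^-1: streamwise and
#'   vertical components.
#' @param U freestream speed, m s^-1.
#' @param f flapping frequency, Hz.
#' @param rho air density, kg m^-3.
#' @param u_var,w_var,uw_cov per-bin velocity variance/covariance fields
#'   (same shape); zeros when absent.
#' @param n_reps repetitions per phase bin (metadata).
#' @return object of class `field_series`.
#' @export
field_series <- function(x, z, u, w, U, f, rho = 1.204,
                         u_var = NULL, w_var = NULL, uw_cov = NULL,
                         n_reps = NA_integer_) {
  check_uniform_grid <- function(g, nm) {
    if (length(g) < 3L) stop(nm, " grid too short")
    d <- diff(g)
    if (any(d <= 0)) stop(nm, " grid must be strictly increasing")
    if (max(d) - min(d) > 1e-9 * max(d)) stop(nm, " grid must be uniform")
  }
  check_uniform_grid(x, "x"); check_uniform_grid(z, "z")
  dm <- dim(u)
  if (length(dm) != 3L || !identical(dm, dim(w)))
    stop("u and w must be 3-d arrays shaped (phase, z, x)")
  if (dm[2L] != length(z) || dm[3L] != length(x))
    stop("velocity arrays shaped (phase, z, x) expected: got dim ",
         paste(dm, collapse = "x"), " for nz = ", length(z),
         ", nx = ", length(x))
  zero <- function(a) if (is.null(a)) array(0, dm) else a
  structure(list(x = x, z = z, u = u, w = w,
                 u_var = zero(u_var), w_var = zero(w_var),
                 uw_cov = zero(uw_cov),
                 U = U, f = f, rho = rho,
                 n_phase = dm[1L], n_reps = n_reps,
                 phase = (seq_len(dm[1L]) - 0.5) / dm[1L]),
            class = "field_series")
}

#' @export
print.field_series <- function(x, ...) {
  cat(sprintf("Field series: %d phase bins, grid %d x %d (x: [%g, %g] m, z: [%g, %g] m)\n",
              x$n_phase, length(x$x), length(x$z),
              min(x$x), max(x$x), min(x$z), max(x$z)))
  cat(sprintf("  U = %g m/s, f = %g Hz, %s reps/bin\n", x$U, x$f, x$n_reps))
  invisible(x)
}

#' Control-volume specification
#'
#' Rectangle within the field domain over which the force budget is
#' evaluated, plus the spanwise jet-width assumption used to
#' dimensionalize the planar (per-unit-depth) force. The default width is
#' twice the handwing length, the lateral extent of the clap jet.
#'
#' @param x_min,x_max,z_min,z_max rectangle bounds, m.
#' @param jet_width assumed spanwise jet width, m (default 2b = 0.2).
#' @param chord wing chord c, m, used in CL = L/(q c).
#' @return object of class `cv_spec`.
#' @export
cv_spec <- function(x_min = -0.2, x_max = 0.2, z_min = -0.15, z_max = 0.15,
                    jet_width = 0.2, chord = 0.2) {
  if (!(x_min < x_max && z_min < z_max)) stop("degenerate control volume")
  stopifnot(jet_width > 0, chord > 0)
  structure(list(x_min = x_min, x_max = x_max, z_min = z_min, z_max = z_max,
                 jet_width = jet_width, chord = chord),
            class = "cv_spec")
}

# Grid indices of the sub-grid spanned by the rectangle (bounds snap
# inward to grid nodes). Errors if the rectangle leaves the domain.
cv_indices <- function(fs, cv) {
  if (cv$x_min < min(fs$x) - 1e-12 || cv$x_max > max(fs$x) + 1e-12 ||
      cv$z_min < min(fs$z) - 1e-12 || cv$z_max > max(fs$z) + 1e-12)
    stop("control volume extends outside the field domain")
  ix <- which(fs$x >= cv$x_min - 1e-12 & fs$x <= cv$x_max + 1e-12)
  iz <- which(fs$z >= cv$z_min - 1e-12 & fs$z <= cv$z_max + 1e-12)
  if (length(ix) < 3L || length(iz) < 3L)
    stop("control volume spans too few grid nodes")
  list(ix = ix, iz = iz)
}

#' Phase-average a snapshot series into a field series
#'
#' Bins raw planar velocity snapshots by fractional phase of the flapping
#' cycle (bin b collects phases in [(b-1)/n, b/n)) and returns per-bin
#' mean fields together with per-bin variance and covariance fields for
#' the turbulent-fluctuation check.
#'
#' @param snaps a snapshot series: list with `x`, `z`, `times` (s) and
#'   arrays `u`, `w` shaped (time, z, x) (as produced by
#'   [make_jet_fields()]).
#' @param f flapping frequency, Hz.
#' @param n_bins number of phase bins (default 83).
#' @param U,rho freestream speed and density metadata (defaults from
#'   `snaps` if present).
#' @return a [field_series()].
#' @export
phase_average <- function(snaps, f = snaps$f, n_bins = 83L,
                          U = snaps$U, rho = if (!is.null(snaps$rho)) snaps$rho else 1.204) {
  n_bins <- as.integer(n_bins)
  times <- snaps$times
  if (is.null(times) || is.null(f)) stop("snapshot times and f are required")
  bin <- floor(((times * f) %% 1) * n_bins) + 1L
  bin[bin > n_bins] <- n_bins  # guard the s == 1 round-off edge
  counts <- tabulate(bin, n_bins)
  if (any(counts == 0L))
    stop("empty phase bin(s): ", paste(which(counts == 0L), collapse = ", "))
  nz <- length(snaps$z); nx <- length(snaps$x)
  um <- wm <- uv <- wv <- uwc <- array(0, c(n_bins, nz, nx))
  for (b in seq_len(n_bins)) {
    i <- which(bin == b)
    ub <- snaps$u[i, , , drop = FALSE]
    wb <- snaps$w[i, , , drop = FALSE]
    mu <- colMeans(ub); mw <- colMeans(wb)
    um[b, , ] <- mu; wm[b, , ] <- mw
    if (length(i) > 1L) {
      n1 <- length(i) - 1L
      du <- sweep(ub, c(2L, 3L), mu)
      dw <- sweep(wb, c(2L, 3L), mw)
      uv[b, , ] <- colSums(du^2) / n1
      wv[b, , ] <- colSums(dw^2) / n1
      uwc[b, , ] <- colSums(du * dw) / n1
    }
  }
  field_series(snaps$x, snaps$z, um, wm, U = U, f = f, rho = rho,
               u_var = uv, w_var = wv, uw_cov = uwc,
               n_reps = as.integer(round(mean(counts))))
}

#' Acceleration term of the control-volume lift budget
#'
#' Rate of change of the downward vertical momentum stored in the control
#' volume, per unit depth:
#' \eqn{\rho\, d/dt \int\!\!\int_{CV} (-w)\, dx\, dz}. The phase
#' derivative uses Savitzky-Golay differentiation (order 2, frame 5),
#' wrapping around the cycle by default. Positive values mean the fluid
#' in the volume is gaining downward momentum — lift on the wing.
#'
#' @param fs a [field_series()].
#' @param cv a [cv_spec()].
#' @param periodic wrap the phase derivative around the cycle? (default
#'   TRUE; the cycle is periodic).
#' @return numeric vector, one value per phase bin, N m^-1.
#' @export
acceleration_term <- function(fs, cv, periodic = TRUE) {
  id <- cv_indices(fs, cv)
  if (fs$n_phase < SG_FRAME)
    stop("need at least ", SG_FRAME, " phase bins for the phase derivative")
  Sz <- vapply(seq_len(fs$n_phase), function(b)
    trapz2d(-fs$w[b, id$iz, id$ix], fs$z[id$iz], fs$x[id$ix]), numeric(1))
  dt <- 1 / (fs$f * fs$n_phase)
  fs$rho * sg_derivative(Sz, dt, periodic = periodic)
}

#' Momentum-flux term of the control-volume lift budget
#'
#' Net outflow of downward vertical momentum across the four edges of the
#' control rectangle, per unit depth:
#' \eqn{\oint_{CS} \rho\,(-w)\,(\vec v \cdot \hat n)\, dl} with outward
#' normals, integrated by the trapezoidal rule. A uniform freestream
#' contributes zero net flux; a downward jet leaving through the bottom
#' edge contributes positively (lift).
#'
#' @inheritParams acceleration_term
#' @return numeric vector, one value per phase bin, N m^-1.
#' @export
momentum_flux_term <- function(fs, cv) {
  id <- cv_indices(fs, cv)
  ix <- id$ix; iz <- id$iz
  iL <- ix[1L]; iR <- ix[length(ix)]
  iB <- iz[1L]; iT <- iz[length(iz)]
  zs <- fs$z[iz]; xs <- fs$x[ix]
  vapply(seq_len(fs$n_phase), function(b) {
    u <- fs$u[b, , ]; w <- fs$w[b, , ]
    wd <- -w
    right <- trapz1d(wd[iz, iR] * u[iz, iR], zs)     # n = (+1, 0)
    left <- -trapz1d(wd[iz, iL] * u[iz, iL], zs)     # n = (-1, 0)
    top <- trapz1d(wd[iT, ix] * w[iT, ix], xs)       # n = (0, +1)
    bottom <- -trapz1d(wd[iB, ix] * w[iB, ix], xs)   # n = (0, -1)
    fs$rho * (right + left + top + bottom)
  }, numeric(1))
}

# Gauge pressure along one horizontal edge (grid row `irow`), for all
# phases: matrix (phase, x-within-CV). Integrates the inviscid
# streamwise momentum equation dp/dx = -rho (du/dt + u du/dx + w du/dz)
# from the upstream (x_min) corner where p = p_infinity, or applies an
# unsteady Bernoulli closure along the edge.
edge_pressure <- function(fs, ix, irow, method, periodic = TRUE,
                          anchor = "both") {
  xs <- fs$x[ix]
  dxg <- mean(diff(fs$x)); dzg <- mean(diff(fs$z))
  dt <- 1 / (fs$f * fs$n_phase)
  np <- fs$n_phase
  # du/dt on the row (periodic over phase)
  u_row <- fs$u[, irow, ix, drop = FALSE]; dim(u_row) <- c(np, length(ix))
  dudt <- sg_derivative_mat(u_row, dt, periodic = periodic)
  p <- matrix(0, np, length(ix))
  if (method == "momentum_integration") {
    nz <- length(fs$z)
    if (nz < SG_FRAME) stop("z grid too short for du/dz")
    jz <- seq(min(max(1L, irow - 2L), nz - SG_FRAME + 1L), length.out = SG_FRAME)
    for (b in seq_len(np)) {
      ub <- fs$u[b, , ]
      dudx <- sg_derivative(ub[irow, ], dxg)[ix]
      dudz <- sg_derivative_mat(ub[jz, ix, drop = FALSE], dzg)[which(jz == irow), ]
      wrow <- fs$w[b, irow, ix]
      dpdx <- -fs$rho * (dudt[b, ] + ub[irow, ix] * dudx + wrow * dudz)
      p[b, ] <- cumtrapz1d(dpdx, xs)
    }
  } else if (method == "unsteady_bernoulli") {
    for (b in seq_len(np)) {
      s2 <- fs$u[b, irow, ix]^2 + fs$w[b, irow, ix]^2
      p[b, ] <- 0.5 * fs$rho * (fs$U^2 - s2) - fs$rho * cumtrapz1d(dudt[b, ], xs)
      p[b, ] <- p[b, ] - p[b, 1L]  # anchor upstream corner at p_infinity
    }
  } else stop("unknown pressure method: ", method)
  if (anchor == "both") {
    # for a disturbance compact within the edge both corners sit at
    # p_infinity; removing the linear drift suppresses the random-walk
    # error that line integration accumulates from measurement noise
    frac <- (xs - xs[1L]) / (xs[length(xs)] - xs[1L])
    p <- p - outer(p[, length(xs)], frac)
  } else if (anchor != "upstream") stop("unknown anchor: ", anchor)
  p
}

#' Pressure term of the control-volume lift budget
#'
#' Vertical force exerted on the control volume by the gauge pressure on
#' its top and bottom edges, per unit depth:
#' \eqn{\int (p_{bottom} - p_{top})\, dx} (downward-positive budget: high
#' pressure above pushes the jet down and loads the wing). Gauge pressure
#' is recovered from the velocity field along each horizontal edge,
#' anchored at the upstream corner where \eqn{p = p_\infty}:
#' `"momentum_integration"` (default) integrates the inviscid streamwise
#' momentum equation; `"unsteady_bernoulli"` applies an unsteady
#' Bernoulli closure. All derivatives are Savitzky-Golay (order 2,
#' frame 5). With `anchor = "both"` (default) the downstream corner is
#' also pinned to \eqn{p_\infty} and the linear drift between the two
#' anchors removed — appropriate for disturbances compact within the
#' edge (the clap jet) and much more robust to measurement noise, which
#' otherwise accumulates as a random walk along the integration path.
#' Use `anchor = "upstream"` when the flow is still disturbed at the
#' downstream corner.
#'
#' @inheritParams acceleration_term
#' @param method `"momentum_integration"` or `"unsteady_bernoulli"`.
#' @param anchor `"both"` (default) or `"upstream"`.
#' @return numeric vector, one value per phase bin, N m^-1.
#' @export
pressure_term <- function(fs, cv,
                          method = c("momentum_integration", "unsteady_bernoulli"),
                          periodic = TRUE, anchor = "both") {
  method <- match.arg(method)
  id <- cv_indices(fs, cv)
  ix <- id$ix; iz <- id$iz
  xs <- fs$x[ix]
  p_top <- edge_pressure(fs, ix, iz[length(iz)], method, periodic, anchor)
  p_bot <- edge_pressure(fs, ix, iz[1L], method, periodic, anchor)
  vapply(seq_len(fs$n_phase), function(b)
    trapz1d(p_bot[b, ] - p_top[b, ], xs), numeric(1))
}

#' Control-volume lift budget of the clap jet
#'
#' Assembles the three-term control-volume estimate of the vertical force
#' associated with the measured flow: momentum storage (acceleration),
#' boundary momentum flux, and boundary pressure, each per unit depth and
#' positive when loading the wing upward (downward-positive vertical
#' fluid momentum). The per-unit-depth force is dimensionalized by the
#' assumed spanwise jet width (default 2b) and normalized as
#' \eqn{C_L = L / (q c)} with q the freestream dynamic pressure. The
#' turbulent-fluctuation flux
#' \eqn{\oint \rho \langle w' (\vec v' \cdot \hat n)\rangle dl} computed
#' from the per-bin variance fields is reported alongside (not added):
#' with well-converged phase averages it is negligible compared with the
#' mean-flow terms.
#'
#' @inheritParams pressure_term
#' @return object of class `force_budget`: data.frame with columns
#'   `phase`, `accel`, `momentum`, `pressure`, `total` (N m^-1; total is
#'   the exact sum of the three terms), `force` (N, total x jet width),
#'   `CL` (dimensionless) and `turb_flux` (N m^-1).
#' @export
lift_budget <- function(fs, cv,
                        method = c("momentum_integration", "unsteady_bernoulli"),
                        periodic = TRUE, anchor = "both") {
  method <- match.arg(method)
  acc <- acceleration_term(fs, cv, periodic)
  mom <- momentum_flux_term(fs, cv)
  prs <- pressure_term(fs, cv, method, periodic, anchor)
  tot <- acc + mom + prs
  q <- 0.5 * fs$rho * fs$U^2
  id <- cv_indices(fs, cv)
  ix <- id$ix; iz <- id$iz
  iL <- ix[1L]; iR <- ix[length(ix)]; iB <- iz[1L]; iT <- iz[length(iz)]
  turb <- vapply(seq_len(fs$n_phase), function(b) {
    wdu <- -fs$uw_cov[b, , ]   # <w_down' u'> = -<u'w'>
    wdw <- -fs$w_var[b, , ]    # <w_down' w'> = -<w'^2>
    fs$rho * (trapz1d(wdu[iz, iR], fs$z[iz]) - trapz1d(wdu[iz, iL], fs$z[iz]) +
              trapz1d(wdw[iT, ix], fs$x[ix]) - trapz1d(wdw[iB, ix], fs$x[ix]))
  }, numeric(1))
  out <- data.frame(phase = fs$phase, accel = acc, momentum = mom,
                    pressure = prs, total = tot,
                    force = tot * cv$jet_width,
                    CL = tot / (q * cv$chord),
                    turb_flux = turb)
  structure(out, class = c("force_budget", "data.frame"),
            cv = cv, U = fs$U, f = fs$f, rho = fs$rho, method = method)
}

#' Peak lift coefficient during the wing clap
#'
#' The clap lift coefficient is the local peak of CL(phase) within the
#' clapping window (default t/T in [0.7, 0.9]).
#'
#' @param budget a `force_budget` (or data.frame with `phase` and `CL`).
#' @param window numeric length 2 within [0, 1): phase window searched.
#' @return list with `CL_clap` and `phase` of the peak.
#' @export
clap_peak <- function(budget, window = c(0.7, 0.9)) {
  if (length(window) != 2L || window[1L] >= window[2L])
    stop("clap window must be an increasing pair of cycle fractions")
  i <- which(budget$phase >= window[1L] & budget$phase <= window[2L])
  if (!length(i)) stop("no phase bins inside the clap window")
  j <- i[which.max(budget$CL[i])]
  list(CL_clap = budget$CL[j], phase = budget$phase[j])
}
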