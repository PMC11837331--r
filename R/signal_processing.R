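#' Force/power trace from a wind-tunnel trial
#'
#' Measured time series from one trial: vertical force from the
#' force/torque transducer (1000 Hz) and mechanical motor power (angular
#' velocity x torque, 512 Hz). Trials are either `wings_on` (inertia +
#' aerodynamics) or `wings_off` (handwings removed: mechanism inertia
#' only); their difference is the net aerodynamic trace.
#'
#' @param force_time,Fz force-channel time stamps (s) and vertical force (N).
#' @param power_time,P power-channel time stamps (s) and power (W).
#' @param condition `"wings_on"`, `"wings_off"` or `"net"`.
#' @param f flapping frequency, Hz.
#' @param theta0 fold amplitude, rad.
#' @param U freestream speed, m s^-1.
#' @return object of class `force_trace`.
#' @export
force_trace <- function(force_time, Fz, power_time, P,
                        condition = c("wings_on", "wings_off", "net"),
                        f, theta0 = 0, U = 4) {
  condition <- match.arg(condition)
  fr <- 1 / check_uniform_time(force_time, "force time")
  pr <- 1 / check_uniform_time(power_time, "power time")
  if (length(Fz) != length(force_time) || length(P) != length(power_time))
    stop("channel lengths do not match their time vectors")
  structure(list(force = data.frame(time = force_time, Fz = Fz),
                 power = data.frame(time = power_time, P = P),
                 force_rate = fr, power_rate = pr,
                 condition = condition, f = f, theta0 = theta0, U = U),
            class = "force_trace")
}

#' Zero-phase Butterworth low-pass filter
#'
#' Forward-backward (zero-phase) Butterworth low-pass with cut-off
#' \eqn{f_c = 5 f} (15 Hz at the 3 Hz flapping frequency), preserving the
#' amplitude and phase of the flapping fundamental while removing
#' transducer resonance and noise. Odd-reflection padding suppresses the
#' end transients of the forward-backward pass; DC gain is 1.
#'
#' @param x numeric vector, or a [force_trace()] (both channels filtered
#'   at their own sample rates).
#' @param fs sample rate, Hz (vector input only).
#' @param f flapping frequency, Hz; the cut-off is `5 * f`.
#' @param order filter order (default 4).
#' @return filtered object of the same type.
#' @export
butterworth_lowpass <- function(x, fs, f, order = 4L) {
  if (inherits(x, "force_trace")) {
    x$force$Fz <- butterworth_lowpass(x$force$Fz, x$force_rate, f = x$f, order = order)
    x$power$P <- butterworth_lowpass(x$power$P, x$power_rate, f = x$f, order = order)
    return(x)
  }
  fc <- 5 * f
  if (fc >= fs / 2)
    stop("cut-off fc = 5f = ", fc, " Hz is at or above the Nyquist frequency ",
         fs / 2, " Hz")
  bf <- signal::butter(order, fc / (fs / 2), type = "low")
  n <- length(x)
  np <- min(n - 1L, max(50L, ceiling(3 * fs / fc)))
  xp <- c(2 * x[1L] - rev(x[2L:(np + 1L)]), x,
          2 * x[n] - rev(x[(n - np):(n - 1L)]))
  signal::filtfilt(bf, xp)[(np + 1L):(np + n)]
}

#' Subtract mechanism inertia using a matched wings-off trial
#'
#' The wings-off trial repeats the wings-on trial with the handwings
#' removed, recording the inertial forces of the moving mechanism alone.
#' Both traces are low-pass filtered (cut-off 5f), optionally
#' phase-aligned on the flap-synchronous component by cross-correlation,
#' and differenced: the result is the net aerodynamic force and power.
#'
#' Cross-correlation alignment recovers a gross trigger offset between
#' trials, but because the wings-on fundamental is the sum of the
#' inertial and aerodynamic components, its estimated lag is pulled by
#' the aerodynamic phase; with hardware-trigger-synchronized trials
#' (`align = FALSE`) the trace-level recovery is noise-limited. The
#' misalignment residual is a circularly shifted periodic signal, so
#' cycle-averaged coefficients are unaffected either way.
#'
#' @param on,off [force_trace()] objects with conditions `"wings_on"` and
#'   `"wings_off"`, matched in f, sample rates and duration.
#' @param align phase-align the wings-off trace by cross-correlation
#'   before subtracting?
#' @return a `"net"` [force_trace()].
#' @export
subtract_inertia <- function(on, off, align = TRUE) {
  stopifnot(inherits(on, "force_trace"), inherits(off, "force_trace"))
  if (on$condition != "wings_on" || off$condition != "wings_off")
    stop("expected conditions wings_on and wings_off, got ",
         on$condition, " and ", off$condition)
  if (abs(on$f - off$f) > 1e-9) stop("flapping frequencies differ between trials")
  if (abs(on$force_rate - off$force_rate) > 1e-6 ||
      abs(on$power_rate - off$power_rate) > 1e-6)
    stop("sample rates differ between trials")
  if (nrow(on$force) != nrow(off$force) || nrow(on$power) != nrow(off$power))
    stop("trial durations differ")
  onf <- butterworth_lowpass(on)
  offf <- butterworth_lowpass(off)
  shift <- 0L
  if (align) {
    max_lag <- floor(on$force_rate / on$f / 2)  # within +- half a cycle
    cc <- stats::ccf(onf$force$Fz, offf$force$Fz, lag.max = max_lag,
                     plot = FALSE, demean = TRUE)
    shift <- cc$lag[which.max(cc$acf)]
  }
  # result[i] = v[i - k] with circular wrap (traces cover whole cycles)
  roll <- function(v, k) {
    n <- length(v); k <- ((k %% n) + n) %% n
    if (k == 0) v else c(v[(n - k + 1L):n], v[1L:(n - k)])
  }
  fz_off <- roll(offf$force$Fz, as.integer(shift))
  p_shift <- as.integer(round(shift / on$force_rate * on$power_rate))
  p_off <- roll(offf$power$P, p_shift)
  force_trace(on$force$time, onf$force$Fz - fz_off,
              on$power$time, onf$power$P - p_off,
              condition = "net", f = on$f, theta0 = on$theta0, U = on$U)
}

#' Normalize a net aerodynamic trace to lift and power coefficients
#'
#' \eqn{C_L = F_z / (\tfrac12 \rho U^2 S)} and
#' \eqn{C_P = P / (\tfrac12 \rho U^3 S)} with \eqn{S = 2bc}. The power
#' channel (512 Hz) is resampled onto the force clock (1000 Hz) by linear
#' interpolation so the two coefficients share one time base.
#'
#' @param net a `"net"` [force_trace()].
#' @param rho air density, kg m^-3.
#' @param U freestream speed, m s^-1 (default from the trace).
#' @param S reference area 2bc, m^2.
#' @return data.frame `time`, `CL`, `CP` with attribute `f`; class
#'   `force_power_series` so [cycle_average()] applies.
#' @export
normalize_trace <- function(net, rho = 1.204, U = net$U, S = 0.04) {
  stopifnot(rho > 0, U > 0, S > 0)
  q <- 0.5 * rho * U^2
  P_on_force_clock <- approx(net$power$time, net$power$P,
                             xout = net$force$time, rule = 2)$y
  out <- data.frame(time = net$force$time,
                    CL = net$force$Fz / (q * S),
                    CP = P_on_force_clock / (q * U * S))
  structure(out, class = c("force_power_series", "data.frame"),
            f = net$f, U = U)
}

#' Strouhal numbers of the flapping and clapping motion
#'
#' `strouhal()` is the classical flapping Strouhal number St = f A / U,
#' with A the peak-to-peak vertical wingtip excursion of the unfolded
#' wing. `strouhal_clap()` is the local clap analogue
#' St_clap = f theta0 b / U built on the handwing tip speed scale
#' f theta0 b; theta0 must be in radians for this to be a velocity ratio.
#'
#' @param f flapping frequency, Hz.
#' @param A no-fold peak-to-peak tip excursion, m.
#' @param U freestream speed, m s^-1 (> 0).
#' @param theta0 fold amplitude, rad.
#' @param b handwing length, m.
#' @return the dimensionless ratio.
#' @export
strouhal <- function(f, A, U) {
  if (!isTRUE(all(U > 0))) stop("freestream U must be positive")
  stopifnot(f > 0, A > 0)
  f * A / U
}

#' @rdname strouhal
#' @export
strouhal_clap <- function(f, theta0, b, U) {
  if (!isTRUE(all(U > 0))) stop("freestream U must be positive")
  stopifnot(f > 0, b > 0, theta0 >= 0)
  f * theta0 * b / U
}

#' Phase-average a trace over the flapping cycle
#'
#' Bins samples of a cyclic signal by fractional phase (same binning rule
#' as [phase_average()]) and returns per-bin means with a standard
#' deviation band measuring the cycle-to-cycle spread: samples are first
#' averaged within each (bin, cycle) pair, and the band is the standard
#' deviation of those per-cycle values across cycles — the shading drawn
#' around phase-averaged force traces. A noise-free periodic signal
#' therefore has a zero band even when several samples of differing
#' phase fall in one bin.
#'
#' @param x numeric vector of samples.
#' @param time sample times, s (uniform).
#' @param f flapping frequency, Hz.
#' @param n_bins number of phase bins (default 83).
#' @return data.frame `phase` (bin centres), `mean`, `sd`
#'   (cycle-to-cycle), `n` (samples per bin).
#' @export
phase_average_trace <- function(x, time, f, n_bins = 83L) {
  dt <- check_uniform_time(time)
  span <- length(time) * dt * f
  if (span < 1 - 1e-9) stop("need at least one full cycle to phase-average")
  n_bins <- as.integer(n_bins)
  ph <- time * f
  bin <- floor((ph %% 1) * n_bins) + 1L
  bin[bin > n_bins] <- n_bins
  cyc <- floor(ph)
  percyc <- tapply(x, list(bin, cyc), mean)     # bin x cycle means
  mn <- tapply(x, bin, mean)
  sdv <- apply(percyc, 1L, function(v) {
    v <- v[!is.na(v)]
    if (length(v) > 1L) sd(v) else 0
  })
  n <- tapply(x, bin, length)
  idx <- as.integer(names(mn))
  data.frame(phase = (idx - 0.5) / n_bins,
             mean = as.numeric(mn), sd = as.numeric(sdv),
             n = as.integer(n))
}

#' Scaling of the clap lift coefficient with the clap Strouhal number
#'
#' Least-squares slope and Spearman rank correlation of CL_clap against
#' St_clap over a family of conditions. The monotone trend is reported,
#' not asserted.
#'
#' @param St_clap,CL_clap numeric vectors (>= 3 points).
#' @return list with `slope`, `intercept`, `spearman_rho`, `n`.
#' @export
clap_scaling <- function(St_clap, CL_clap) {
  if (length(St_clap) < 3L || length(CL_clap) != length(St_clap))
    stop("need at least 3 matched (St_clap, CL_clap) points")
  if (sd(St_clap) == 0) stop("degenerate St_clap values: no spread")
  fit <- lm(CL_clap ~ St_clap)
  rho <- if (sd(CL_clap) == 0) 0 else cor(St_clap, CL_clap, method = "spearman")
  list(slope = unname(coef(fit)[2L]),
       intercept = unname(coef(fit)[1L]),
       spearman_rho = rho,
       n = length(St_clap))
}
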