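#' @importFrom stats approx coef cor lm sd var setNames
#' @importFrom utils modifyList read.csv write.csv
NULL

# Savitzky-Golay smoothing/differentiation used throughout the pipeline:
# order 2, frame length 5, which is exact for sampled quadratics.
SG_ORDER <- 2L
SG_FRAME <- 5L

#' Savitzky-Golay derivative of a uniformly sampled series
#'
#' Differentiates a sampled signal with a Savitzky-Golay filter
#' (order 2, frame length 5). With `periodic = TRUE` the series is taken
#' as one period of a cyclic signal and the frame wraps around the ends;
#' otherwise the filter's one-sided edge rows are used.
#'
#' @param x numeric vector, uniformly sampled.
#' @param dt sample spacing (s).
#' @param periodic wrap the frame around the ends of the series?
#' @return numeric vector of the same length: dx/dt at each sample.
#' @export
sg_derivative <- function(x, dt, periodic = FALSE) {
  n <- length(x)
  if (n < SG_FRAME)
    stop("need at least ", SG_FRAME, " samples for Savitzky-Golay differentiation, got ", n)
  if (!isTRUE(dt > 0)) stop("dt must be positive")
  if (periodic) {
    h <- (SG_FRAME - 1L) %/% 2L
    xp <- c(x[(n - h + 1L):n], x, x[1L:h])
    d <- signal::sgolayfilt(xp, p = SG_ORDER, n = SG_FRAME, m = 1L, ts = dt)
    d[(h + 1L):(h + n)]
  } else {
    signal::sgolayfilt(x, p = SG_ORDER, n = SG_FRAME, m = 1L, ts = dt)
  }
}

# Apply sg_derivative along the first margin of a matrix (columns are
# independent series). Used for phase-wise derivatives of gridded fields.
sg_derivative_mat <- function(m, dt, periodic = FALSE) {
  apply(m, 2L, sg_derivative, dt = dt, periodic = periodic)
}

# Trapezoidal weights for a (possibly non-uniform) monotone grid.
trapz_weights <- function(g) {
  n <- length(g)
  if (n < 2L) stop("grid too short for trapezoidal integration")
  w <- numeric(n)
  d <- diff(g)
  w[1L] <- d[1L] / 2
  w[n] <- d[n - 1L] / 2
  if (n > 2L) w[2L:(n - 1L)] <- (d[-(n - 1L)] + d[-1L]) / 2
  w
}

# 2-D trapezoid over a field f indexed [z, x].
trapz2d <- function(f, z, x) {
  wz <- trapz_weights(z)
  wx <- trapz_weights(x)
  as.numeric(wz %*% f %*% wx)
}

trapz1d <- function(f, g) sum(trapz_weights(g) * f)

# Cumulative trapezoid with value 0 at the first node.
cumtrapz1d <- function(f, g) {
  n <- length(f)
  c(0, cumsum(diff(g) * (f[-n] + f[-1L]) / 2))
}

check_uniform_time <- function(time, what = "time") {
  if (length(time) < 2L) stop(what, " needs at least 2 samples")
  dt <- diff(time)
  if (any(dt <= 0)) stop(what, " must be strictly increasing")
  if (max(dt) - min(dt) > 1e-9 * max(abs(dt)) + 1e-15)
    stop(what, " must be uniformly sampled")
  mean(dt)
}

# Evaluate with a private, seeded RNG stream; the caller's stream is
# untouched so generators are pure functions of (spec, seed).
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Linear interpolation that treats `xf` as a cyclic coordinate on [0, 1).
interp_periodic <- function(xf, y, xout) {
  o <- order(xf)
  xf <- xf[o]; y <- y[o]
  xx <- c(xf[length(xf)] - 1, xf, xf[1L] + 1)
  yy <- c(y[length(y)], y, y[1L])
  approx(xx, yy, xout = xout %% 1)$y
}
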