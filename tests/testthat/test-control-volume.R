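# Control-volume force estimation: phase averaging, the three budget
# terms against closed forms and refined oracles, and the assembled
# clap-jet lift.

test_that("phase averaging: stationary fields reproduce the snapshot with zero variance", {
  x <- seq(-0.1, 0.1, by = 0.02); z <- seq(-0.1, 0.1, by = 0.02)
  nt <- 200L
  snap <- matrix(rnorm(length(z) * length(x)), length(z), length(x))
  u <- array(rep(snap, each = nt), c(nt, length(z), length(x)))
  snaps <- list(x = x, z = z, times = (0:(nt - 1)) / 100, u = u, w = u * 0,
                U = 4, f = 2)
  fs <- phase_average(snaps, n_bins = 10L)
  for (b in 1:10) expect_equal(fs$u[b, , ], snap)
  expect_equal(max(abs(fs$u_var)), 0)
  expect_equal(max(abs(fs$uw_cov)), 0)
})

test_that("phase averaging of a sinusoid matches the analytic bin-average", {
  f <- 3; fs_hz <- 500; n_cycles <- 40L; n_bins <- 83L
  nt <- round(n_cycles * fs_hz / f)
  tt <- (0:(nt - 1)) / fs_hz
  A <- 2
  sig <- A * sin(2 * pi * f * tt)
  u <- array(rep(sig, 9L), c(nt, 3L, 3L))
  snaps <- list(x = 1:3 / 100, z = 1:3 / 100, times = tt, u = u, w = u * 0,
                U = 4, f = f)
  fs <- phase_average(snaps, n_bins = n_bins)
  # oracle: mean of sin over bin [a, b] = (cos a - cos b)/(b - a)
  edges <- 2 * pi * (0:n_bins) / n_bins
  want <- A * (cos(edges[-(n_bins + 1)]) - cos(edges[-1])) / diff(edges)
  expect_equal(fs$u[, 2, 2], want, tolerance = 0.02)
})

test_that("phase averaging errors on empty bins, listing them", {
  snaps <- list(x = 1:3 / 10, z = 1:3 / 10,
                times = c(0, 0.001, 0.002),  # all in the first bin
                u = array(1, c(3, 3, 3)), w = array(0, c(3, 3, 3)),
                U = 4, f = 3)
  expect_error(phase_average(snaps, n_bins = 10L), "empty phase bin")
})

test_that("acceleration term: zero for steady fields, exact for a linear ramp", {
  fs <- fix_uniform_field()
  cv <- cv_spec()
  expect_equal(acceleration_term(fs, cv), rep(0, 83))

  # downward flow ramping linearly in time, uniform in space:
  # rho * a * A_cv, exact for the order-2 filter (non-periodic ramp)
  a <- 2.5; f <- 3; np <- 21L
  ph <- (seq_len(np) - 0.5) / np
  fs2 <- fix_field_from_fun(function(s, x, z)
    list(u = matrix(4, length(z), length(x)),
         w = matrix(-a * s / f, length(z), length(x))), n_phase = np)
  acc <- acceleration_term(fs2, cv, periodic = FALSE)
  A_cv <- (cv$x_max - cv$x_min) * (cv$z_max - cv$z_min)
  expect_equal(acc, rep(1.204 * a * A_cv, np), tolerance = 1e-10)
  expect_error(acceleration_term(fs2, cv_spec(-1, 1, -1, 1)), "outside")
})

test_that("acceleration term on a smooth jet pulse matches a dense finite-difference oracle", {
  sp <- fix_jet_spec()
  cv <- cv_spec()
  np <- 830L  # finely phase-resolved so the operator, not the binning, is tested
  fs <- fix_field_from_fun(function(s, x, z) wingclap:::jet_field_at(sp, s, x, z),
                           n_phase = np)
  acc <- acceleration_term(fs, cv)
  # oracle: 10x-resolution central differences of the analytic volume integral
  S_of <- function(s) {
    fl <- wingclap:::jet_field_at(sp, s, seq(cv$x_min, cv$x_max, by = 0.0025),
                                  seq(cv$z_min, cv$z_max, by = 0.0025))
    wingclap:::trapz2d(-fl$w, seq(cv$z_min, cv$z_max, by = 0.0025),
                       seq(cv$x_min, cv$x_max, by = 0.0025))
  }
  h <- 1e-4
  ph <- fs$phase
  want <- vapply(ph, function(s)
    1.204 * (S_of(s + h) - S_of(s - h)) / (2 * h) * sp$f, numeric(1))
  expect_lt(max(abs(acc - want)) / max(abs(want)), 0.01)
})

test_that("momentum flux: zero in uniform freestream, hand integral for a bottom-edge jet", {
  cv <- cv_spec()
  expect_equal(momentum_flux_term(fix_uniform_field(), cv), rep(0, 83))

  # uniform downward flow crossing only the bottom edge
  W <- 1.5
  fs <- fix_field_from_fun(function(s, x, z) {
    w <- matrix(0, length(z), length(x))
    w[1, ] <- -W             # bottom row of the domain (= CV bottom edge)
    list(u = matrix(0, length(z), length(x)), w = w)
  }, n_phase = 7L, z = seq(cv_spec()$z_min, 0.2, by = 0.01))
  ell <- cv$x_max - cv$x_min
  expect_equal(momentum_flux_term(fs, cv), rep(1.204 * W^2 * ell, 7L),
               tolerance = 1e-12)
})

test_that("momentum flux on the synthetic jet matches a 4x-refined quadrature oracle", {
  sp <- fix_jet_spec()
  # off-centre CV: a centred box around the symmetric jet cancels exactly,
  # so put the bottom edge close under the core to get a real net flux
  cv <- cv_spec(-0.1, 0.2, -0.05, 0.18)
  s_clap <- 0.8
  fs2 <- fix_field_from_fun(function(s, x, z)
    wingclap:::jet_field_at(sp, s_clap, x, z), n_phase = 5L)
  got <- momentum_flux_term(fs2, cv)[1L]
  edge <- function(g, vals) wingclap:::trapz1d(vals, g)
  xf <- seq(cv$x_min, cv$x_max, by = 0.0025)
  zf <- seq(cv$z_min, cv$z_max, by = 0.0025)
  fl_r <- wingclap:::jet_field_at(sp, s_clap, cv$x_max, zf)
  fl_l <- wingclap:::jet_field_at(sp, s_clap, cv$x_min, zf)
  fl_t <- wingclap:::jet_field_at(sp, s_clap, xf, cv$z_max)
  fl_b <- wingclap:::jet_field_at(sp, s_clap, xf, cv$z_min)
  want <- 1.204 * (edge(zf, -fl_r$w * fl_r$u) - edge(zf, -fl_l$w * fl_l$u) +
                   edge(xf, -fl_t$w * fl_t$w) - edge(xf, -fl_b$w * fl_b$w))
  expect_lt(abs(got - want) / abs(want), 0.01)
})

test_that("pressure recovery: zero in uniform freestream; Bernoulli closed form on steady potential flow", {
  cv <- cv_spec()
  expect_equal(max(abs(pressure_term(fix_uniform_field(), cv))), 0)

  # steady irrotational perturbation: u = U - eps*k*e^{kz} sin(kx),
  # w = eps*k*e^{kz} cos(kx); p = p_inf + rho/2 (U^2 - |v|^2)
  U <- 4; eps <- 0.02; k <- 5; rho <- 1.204
  pot <- function(s, x, z) {
    list(u = U - eps * k * outer(exp(k * z), sin(k * x)),
         w = eps * k * outer(exp(k * z), cos(k * x)))
  }
  fs <- fix_field_from_fun(pot, n_phase = 7L, U = U)
  p_edge <- function(zc) {
    xs <- seq(cv$x_min, cv$x_max, by = 0.01)
    s2 <- (U - eps * k * exp(k * zc) * sin(k * xs))^2 +
      (eps * k * exp(k * zc) * cos(k * xs))^2
    p <- 0.5 * rho * (U^2 - s2)
    p - p[1L]  # same upstream-corner anchoring as the estimator
  }
  xs <- seq(cv$x_min, cv$x_max, by = 0.01)
  want <- wingclap:::trapz1d(p_edge(cv$z_min) - p_edge(cv$z_max), xs)
  # the perturbation is not compact, so anchor at the upstream corner only
  got_mi <- pressure_term(fs, cv, "momentum_integration", anchor = "upstream")
  got_ub <- pressure_term(fs, cv, "unsteady_bernoulli", anchor = "upstream")
  expect_equal(got_mi[4L], want, tolerance = 0.01)
  expect_equal(got_ub[4L], want, tolerance = 1e-6)
  expect_error(pressure_term(fs, cv, "vorticity"), "momentum_integration")
})

test_that("the two pressure methods agree on the synthetic jet at the clap", {
  sp <- fix_jet_spec()
  cv <- cv_spec(-0.08, 0.08, -0.06, 0.06)
  fs <- fix_field_from_fun(function(s, x, z) wingclap:::jet_field_at(sp, s, x, z),
                           n_phase = 83L)
  p_mi <- pressure_term(fs, cv, "momentum_integration")
  p_ub <- pressure_term(fs, cv, "unsteady_bernoulli")
  bud <- lift_budget(fs, cv)
  i <- which(bud$phase == clap_peak(bud)$phase)
  expect_lt(abs(p_mi[i] - p_ub[i]), 0.05 * abs(bud$total[i]))
})

test_that("budget identity holds exactly and uniform freestream gives CL = 0 at every phase", {
  fs <- fix_uniform_field()
  bud <- lift_budget(fs, cv_spec())
  expect_equal(bud$total, bud$accel + bud$momentum + bud$pressure)
  expect_equal(max(abs(bud$CL)), 0)
})

test_that("clap-jet peak CL is recovered within 5% of the generator's analytic budget", {
  sp <- fix_jet_spec(seed = 11L, n_cycles = 8L)
  jf <- make_jet_fields(sp)
  fs <- phase_average(jf$snapshots, n_bins = 83L)
  cv <- cv_spec()
  bud <- lift_budget(fs, cv)
  truth <- jf$truth_fun(cv)
  pk <- clap_peak(bud); pk_t <- clap_peak(truth)
  expect_lt(abs(pk$CL_clap - pk_t$CL_clap) / abs(pk_t$CL_clap), 0.05)
  # budget identity on real pipeline output
  expect_equal(bud$total, bud$accel + bud$momentum + bud$pressure)
})

test_that("peak CL is insensitive to the control-volume rectangle once the jet is enclosed", {
  sp <- fix_jet_spec(seed = 12L, n_cycles = 6L)
  jf <- make_jet_fields(sp)
  fs <- phase_average(jf$snapshots, n_bins = 83L)
  peaks <- sapply(c(0.7, 1, 1.3), function(sc)
    clap_peak(lift_budget(fs, cv_spec(-0.2 * sc, 0.2 * sc,
                                      -0.145 * sc, 0.145 * sc)))$CL_clap)
  expect_lt((max(peaks) - min(peaks)) / abs(mean(peaks)), 0.05)
})

test_that("a Galilean shift of the streamwise velocity barely changes the jet lift", {
  sp <- fix_jet_spec(seed = 13L, n_cycles = 6L)
  jf <- make_jet_fields(sp)
  fs <- phase_average(jf$snapshots, n_bins = 83L)
  cv <- cv_spec()
  pk0 <- clap_peak(lift_budget(fs, cv))$CL_clap
  fs$u <- fs$u + 1.5
  pk1 <- clap_peak(lift_budget(fs, cv))$CL_clap
  expect_lt(abs(pk1 - pk0) / abs(pk0), 0.02)
})

test_that("total lift converges with joint grid and phase-bin refinement on the analytic jet", {
  # spatial quadrature of the smooth Gaussian is near-converged already,
  # so refinement must sharpen the phase axis too to expose the dominant
  # (phase-derivative) discretization error
  sp <- fix_jet_spec()
  cv <- cv_spec(-0.18, 0.18, -0.14, 0.14)
  peak_at <- function(dx, np) {
    fs <- fix_field_from_fun(function(s, x, z) wingclap:::jet_field_at(sp, s, x, z),
                             n_phase = np,
                             x = seq(-0.3, 0.3, by = dx),
                             z = seq(-0.2, 0.2, by = dx))
    clap_peak(lift_budget(fs, cv))$CL_clap
  }
  truth <- clap_peak(jet_truth_budget(sp, cv, n_phase = 830L, refine = 8L))$CL_clap
  err <- abs(c(peak_at(0.04, 83L), peak_at(0.02, 166L), peak_at(0.01, 332L)) - truth)
  expect_true(all(diff(err) < 0))
  expect_gt(err[1] / err[3], 2)   # at least ~1st-order decay over 4x refinement
})

test_that("turbulent-flux report is exactly zero for zero-variance input and clap_peak honours its window", {
  fs <- fix_uniform_field()
  bud <- lift_budget(fs, cv_spec())
  expect_equal(max(abs(bud$turb_flux)), 0)

  ph <- (1:83 - 0.5) / 83
  fake <- data.frame(phase = ph,
                     CL = 2 * exp(-(ph - 0.5)^2 / 1e-3) +
                          exp(-(ph - 0.8)^2 / 1e-3))
  pk <- clap_peak(fake, window = c(0.7, 0.9))
  expect_equal(pk$phase, ph[which.min(abs(ph - 0.8))])
  expect_lt(abs(pk$CL_clap - 1), 0.05)
  expect_equal(clap_peak(data.frame(phase = ph, CL = 0 * ph))$CL_clap, 0)
  expect_error(clap_peak(fake, window = c(0.9, 0.7)), "window")
})
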