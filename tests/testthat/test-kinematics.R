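# Wing kinematics: flap/fold generators, realized-motion emulation,
# blade-element states.

test_that("sinusoidal flap has the dorsal extreme at t = 0 and the ventral at T/2", {
  f <- 3; Phi <- 0.77
  expect_equal(commanded_flap(0, f, Phi), Phi)
  expect_equal(commanded_flap(1 / (2 * f), f, Phi), -Phi)
  # downstroke: phi decreasing over the first half-cycle
  t <- seq(0, 1 / (2 * f), length.out = 50)
  expect_true(all(diff(commanded_flap(t, f, Phi)) < 0))
  expect_error(commanded_flap(0.1, 0, Phi), "frequency")
})

test_that("commanded motion is periodic to machine precision", {
  f <- 3
  t <- seq(0, 1 / f, length.out = 97)
  for (th0 in c(0, 1.0)) {
    expect_equal(commanded_flap(t + 1 / f, f, 0.7), commanded_flap(t, f, 0.7))
    expect_equal(commanded_fold(t + 1 / f, f, th0), commanded_fold(t, f, th0),
                 tolerance = 1e-12)
  }
})

test_that("four-bar rocker matches an independent loop-closure root solve and its toggle angles", {
  links <- list(crank = 20, coupler = 100, rocker = 60, ground = 110)
  # independent oracle: solve |C + r e^{i gamma} - A| = coupler by root
  # finding in the rocker angle, for each crank angle
  oracle <- function(beta) {
    a <- 20; l <- 100; r <- 60; d <- 110
    ax <- a * cos(beta); az <- a * sin(beta)
    fn <- function(g) (d + r * cos(g) - ax)^2 + (r * sin(g) - az)^2 - l^2
    stats::uniroot(fn, c(1e-6, pi - 1e-6), tol = 1e-12)$root
  }
  betas <- seq(0, 2 * pi, length.out = 181L)
  got <- fourbar_rocker_angle(betas, links)
  want <- vapply(betas, oracle, numeric(1))
  expect_equal(got, want, tolerance = 1e-8)

  dense <- fourbar_rocker_angle(seq(0, 2 * pi, length.out = 20001L), links)
  tog <- fourbar_toggle_angles(links)
  expect_equal(min(dense), tog[["min"]], tolerance = 1e-6)
  expect_equal(max(dense), tog[["max"]], tolerance = 1e-6)
})

test_that("non-Grashof linkages are rejected naming the violated inequality", {
  expect_error(check_grashof(list(crank = 50, coupler = 60, rocker = 55, ground = 45)),
               "shortest")
  expect_error(check_grashof(list(crank = 10, coupler = 20, rocker = 25, ground = 100)),
               "crank \\+ longest")
})

test_that("fourbar flap mode starts at the dorsal extreme with the requested half-amplitude", {
  links <- list(crank = 20, coupler = 100, rocker = 60, ground = 110)
  f <- 3; Phi <- 0.77
  t <- seq(0, 1 / f, length.out = 400L)
  phi <- commanded_flap(t, f, Phi, mode = "fourbar", links = links)
  expect_equal(phi[1L], max(phi))
  expect_equal(max(phi) - min(phi), 2 * Phi, tolerance = 1e-3)
  expect_error(commanded_flap(t, f, Phi, mode = "fourbar"), "link")
})

test_that("fold pulse is zero before onset, peaks at theta0, returns to zero, C1 at onset", {
  f <- 3; th0 <- 100 * pi / 180
  expect_equal(commanded_fold(seq(0, 1, by = 0.01), f, 0), rep(0, 101))
  expect_error(commanded_fold(0, f, -0.1), "theta0")
  # peak value theta0 at t/T = 2/3 for onset 1/3
  expect_equal(commanded_fold((2 / 3) / f, f, th0), th0)
  # zero and flat at onset (C1): numeric derivative at t/T = 1/3
  h <- 1e-7
  th0b <- 60 * pi / 180
  expect_equal(commanded_fold((1 / 3) / f, f, th0b), 0)
  d <- (commanded_fold((1 / 3) / f + h, f, th0b) -
        commanded_fold((1 / 3) / f, f, th0b)) / h
  expect_lt(abs(d), 1e-4)
  # zero at the stroke boundaries
  expect_equal(commanded_fold(0, f, th0), 0)
  expect_lt(commanded_fold(1 / f - 1e-9, f, th0), 1e-6)
})

test_that("realized kinematics: identity without lag, shifted fold peak with lag, bounded wobble", {
  kin <- fix_cycle(theta0 = 100 * pi / 180)
  same <- realized_from_commanded(kin, phase_lag = 0)
  expect_equal(same$fold, kin$fold, tolerance = 1e-12)

  lag <- realized_from_commanded(kin, phase_lag = 0.1)
  s <- (kin$time * kin$f) %% 1
  expect_equal(s[which.max(lag$fold)], 2 / 3 + 0.1, tolerance = 0.01)

  nofold <- realized_from_commanded(fix_cycle(theta0 = 0), phase_lag = 0.1)
  expect_gte(min(nofold$fold), -20 * pi / 180 - 1e-12)
  expect_lte(max(nofold$fold), 5 * pi / 180 + 1e-12)
  expect_error(realized_from_commanded(kin, phase_lag = 0.5), "phase_lag")
})

test_that("element states: static wing sees the freestream at zero incidence", {
  t <- seq(0, 1 / 3, length.out = 101L)[-101L]
  kin <- kinematic_series(t, rep(0.3, 100), rep(0.2, 100), f = 3,
                          theta0 = 0.2)
  st <- element_states(kin, fix_geom(), U = 4)
  expect_equal(max(abs(st$w)), 0)
  expect_equal(max(abs(st$alpha_eff)), 0)
  expect_equal(unique(as.numeric(st$U_eff)), 4)
})

test_that("element segments tile the half-span and the tip excursion equals the St amplitude", {
  g <- fix_geom(n_elements = 17L)
  eg <- wingclap:::element_grid(g)
  expect_equal(sum(eg$dr), g$armwing_length + g$handwing_length)

  Phi <- 44 * pi / 180
  kin <- fix_cycle(theta0 = 0, Phi = Phi, n = 1000L)
  st <- element_states(kin, g, U = 4)
  tip <- st$z[, g$n_elements]
  # peak-to-peak tip z of the unfolded wing = A = 2 R sin(Phi), the
  # excursion entering St = f A / U (element station is dr/2 inboard)
  R_tip <- eg$r[g$n_elements]
  expect_equal(max(tip) - min(tip), 2 * R_tip * sin(Phi), tolerance = 1e-6)
})

test_that("tip eAoA at mid-downstroke matches a refined finite-difference oracle", {
  f <- 3; Phi <- 44 * pi / 180; U <- 4
  g <- fix_geom()
  kin <- fix_cycle(theta0 = 0, Phi = Phi, n = 400L)
  st <- element_states(kin, g, U = U)
  i_mid <- which.min(abs(kin$time * f - 0.25))   # mid-downstroke
  j_tip <- g$n_elements
  # oracle: central difference of z(t) at 10x sampling
  r <- wingclap:::element_grid(g)$r[j_tip]
  h <- kin$dt / 10
  tm <- kin$time[i_mid]
  zf <- function(t) r * sin(Phi * cos(2 * pi * f * t))
  w_fd <- (zf(tm + h) - zf(tm - h)) / (2 * h)
  expect_equal(st$alpha_eff[i_mid, j_tip], atan2(-w_fd, U), tolerance = 1e-3)
  expect_equal(st$alpha_eff[i_mid, j_tip], atan(2 * pi * f * Phi * r / U),
               tolerance = 1e-3)
})

test_that("no-fold stroke is mirror-symmetric: w and eAoA flip sign after half a period", {
  kin <- fix_cycle(theta0 = 0, n = 400L)
  st <- element_states(kin, fix_geom(), U = 4)
  half <- 200L
  shift <- function(m) m[c((half + 1):400, 1:half), ]
  expect_equal(shift(st$w), -st$w, tolerance = 1e-10)
  expect_equal(shift(st$alpha_eff), -st$alpha_eff, tolerance = 1e-10)
})

test_that("handwing position is continuous at the wrist", {
  g <- fix_geom(n_elements = 200L)  # fine elements bracket the wrist
  kin <- fix_cycle(theta0 = 100 * pi / 180, n = 50L)
  st <- element_states(kin, g, U = 4)
  iw <- max(which(!st$is_handwing)); ih <- iw + 1L
  expect_lt(max(abs(st$z[, ih] - st$z[, iw])), 2.5 * g$span / 200)
})

test_that("Savitzky-Golay differentiation is exact on sampled quadratics", {
  t <- seq(0, 2, by = 0.05)
  x <- 3 * t^2 - 2 * t + 1
  expect_equal(sg_derivative(x, 0.05), 6 * t - 2, tolerance = 1e-10)
})

test_that("element_states rejects series shorter than the differentiation frame", {
  t <- seq(0, 1/3, length.out = 5L)[-5L]
  kin <- kinematic_series(t, rep(0, 4), rep(0, 4), f = 3)
  expect_error(element_states(kin, fix_geom(), U = 4), "samples")
})
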