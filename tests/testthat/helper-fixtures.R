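# Shared fixtures: small, fast configurations used across test files.
# Everything is generated in code; no stored data.

fix_geom <- function(...) wing_geometry(...)

# one exact cycle of commanded kinematics on n samples
fix_cycle <- function(f = 3, theta0 = 0, Phi = 44 * pi / 180, n = 400L,
                      fold_onset = 1 / 3, cycles = 1L) {
  time <- seq(0, cycles / f, length.out = cycles * n + 1L)[-(cycles * n + 1L)]
  kinematic_series(time,
                   commanded_flap(time, f, Phi),
                   commanded_fold(time, f, theta0, fold_onset),
                   f, theta0 = theta0, fold_onset = fold_onset)
}

# analytic field series sampled noise-free at bin centres
fix_field_from_fun <- function(fun, n_phase = 83L, U = 4, f = 3,
                               x = seq(-0.3, 0.3, by = 0.01),
                               z = seq(-0.2, 0.2, by = 0.01), rho = 1.204) {
  ph <- (seq_len(n_phase) - 0.5) / n_phase
  u <- w <- array(0, c(n_phase, length(z), length(x)))
  for (b in seq_len(n_phase)) {
    fl <- fun(ph[b], x, z)
    u[b, , ] <- fl$u
    w[b, , ] <- fl$w
  }
  field_series(x, z, u, w, U = U, f = f, rho = rho)
}

fix_uniform_field <- function(U = 4, ...) {
  fix_field_from_fun(function(s, x, z)
    list(u = matrix(U, length(z), length(x)),
         w = matrix(0, length(z), length(x))), U = U, ...)
}

# small, fast jet spec (down-scaled trial length; full spatial grid)
fix_jet_spec <- function(seed = 11L, n_cycles = 6L, noise = 0.02, ...)
  synthetic_spec(seed = seed, n_cycles = n_cycles, noise_velocity = noise, ...)
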