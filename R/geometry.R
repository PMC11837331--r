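#' Wing geometry for the flapping-folding wing model
#'
#' Describes one half-wing of the two-degree-of-freedom platform: an inner
#' armwing (shoulder to wrist) and an outer handwing (wrist to tip) of
#' equal chord, discretized into spanwise blade elements. The reference
#' area is that of the two handwings, \eqn{S = 2 b c}, which is the fabric
#' (lifting) surface of the robot: the armwing skeleton is uncovered.
#'
#' @param armwing_length armwing (shoulder-wrist) length, m.
#' @param handwing_length handwing (wrist-tip) length \eqn{b}, m.
#' @param chord chord \eqn{c}, m.
#' @param n_elements number of blade elements per half-wing (>= 4).
#' @param air_density air density \eqn{\rho}, kg m^-3.
#' @return An object of class `wing_geometry`: a list with the arguments
#'   plus `span` (half-wing span) and `S` (reference area, exactly
#'   \eqn{2 b c}).
#' @examples
#' g <- wing_geometry()
#' g$S  # 2 * 0.1 * 0.2 = 0.04 m^2
#' @export
wing_geometry <- function(armwing_length = 0.1, handwing_length = 0.1,
                          chord = 0.2, n_elements = 20L,
                          air_density = 1.204) {
  stopifnot(armwing_length > 0, handwing_length > 0, chord > 0,
            air_density > 0)
  n_elements <- as.integer(n_elements)
  if (n_elements < 4L) stop("n_elements must be >= 4 per half-wing")
  structure(list(
    armwing_length = armwing_length,
    handwing_length = handwing_length,
    chord = chord,
    n_elements = n_elements,
    air_density = air_density,
    span = armwing_length + handwing_length,
    S = 2 * handwing_length * chord
  ), class = "wing_geometry")
}

# Mid-element radial stations and widths; sum(dr) equals the half-span
# exactly so integrated loads see the full wing.
element_grid <- function(geometry) {
  n <- geometry$n_elements
  dr <- geometry$span / n
  r <- (seq_len(n) - 0.5) * dr
  list(r = r, dr = rep(dr, n), is_handwing = r > geometry$armwing_length)
}

#' @export
print.wing_geometry <- function(x, ...) {
  cat("Wing geometry (one half-wing):\n")
  cat(sprintf("  armwing %.3f m + handwing b = %.3f m, chord c = %.3f m\n",
              x$armwing_length, x$handwing_length, x$chord))
  cat(sprintf("  %d elements, reference area S = 2bc = %.4f m^2, rho = %.3f kg/m^3\n",
              x$n_elements, x$S, x$air_density))
  invisible(x)
}
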