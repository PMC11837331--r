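#' Crank-rocker four-bar linkage rocker angle
#'
#' Position solution of a planar four-bar linkage driven by a continuously
#' rotating crank, as used by the flapping drive: the crank pulls a coupler
#' which rocks the armwing link. Link lengths must satisfy the Grashof
#' crank-rocker conditions (the crank is the shortest link and
#' crank + longest <= sum of the other two), otherwise the crank cannot
#' make full revolutions.
#'
#' @param crank_angle crank angle(s), rad, measured from the ground line.
#' @param links named list or vector with `crank`, `coupler`, `rocker`,
#'   `ground` lengths (any consistent unit).
#' @return rocker angle(s), rad, measured from the ground line at the
#'   rocker pivot (elbow-up assembly branch).
#' @seealso [fourbar_toggle_angles()] for the closed-form extrema.
#' @export
fourbar_rocker_angle <- function(crank_angle, links) {
  lk <- check_grashof(links)
  a <- lk[["crank"]]; l <- lk[["coupler"]]; r <- lk[["rocker"]]; d <- lk[["ground"]]
  ax <- a * cos(crank_angle); az <- a * sin(crank_angle)
  # distance from crank pin A to rocker pivot C = (d, 0)
  g <- sqrt((d - ax)^2 + az^2)
  # triangle A-B-C with AB = coupler, CB = rocker
  arg <- (r^2 + g^2 - l^2) / (2 * r * g)
  arg <- pmin(1, pmax(-1, arg))
  beta <- acos(arg)               # angle at C between CA and CB
  gamma <- atan2(az, ax - d)      # direction C -> A
  (gamma - beta) %% (2 * pi)      # elbow-up assembly branch
}

#' Grashof crank-rocker check
#'
#' Validates that a four-bar linkage is a Grashof crank-rocker with the
#' crank as input. Errors name the violated inequality.
#' @inheritParams fourbar_rocker_angle
#' @return the links, invisibly-normalized to a named numeric vector.
#' @export
check_grashof <- function(links) {
  lk <- unlist(links)[c("crank", "coupler", "rocker", "ground")]
  if (anyNA(lk)) stop("links must provide crank, coupler, rocker, ground")
  if (any(lk <= 0)) stop("all link lengths must be positive")
  if (lk[["crank"]] != min(lk))
    stop("not a crank-rocker: crank (", lk[["crank"]],
         ") is not the shortest link (shortest = ", min(lk), ")")
  s <- lk[["crank"]]; L <- max(lk)
  others <- sum(lk) - s - L
  if (s + L > others)
    stop("Grashof condition violated: crank + longest = ", s + L,
         " > sum of remaining links = ", others)
  lk
}

#' Closed-form rocker extreme (toggle) angles of a crank-rocker
#'
#' At the rocker extremes the crank and coupler are collinear (extended,
#' length coupler + crank, and folded, coupler - crank), giving the toggle
#' angles from the law of cosines.
#' @inheritParams fourbar_rocker_angle
#' @return named vector `c(min, max)` of rocker angles, rad.
#' @export
fourbar_toggle_angles <- function(links) {
  lk <- check_grashof(links)
  a <- lk[["crank"]]; l <- lk[["coupler"]]; r <- lk[["rocker"]]; d <- lk[["ground"]]
  ang <- function(ob) {
    arg <- (d^2 + r^2 - ob^2) / (2 * d * r)
    if (abs(arg) > 1) stop("linkage cannot be assembled at a toggle position")
    pi - acos(arg)  # rocker angle from +x axis at the rocker pivot
  }
  th <- sort(c(ang(l + a), ang(l - a)))
  c(min = th[1L], max = th[2L])
}
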