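#' Hyperbolic distance between points on the Poincare disk
#'
#' Distance in the native (polar) representation of the hyperbolic plane of
#' curvature `-zeta^2`:
#' `cosh(zeta * d) = cosh(zeta*r1) cosh(zeta*r2) - sinh(zeta*r1) sinh(zeta*r2) cos(dtheta)`,
#' with `dtheta` the circle distance between the two angles.  The `acosh`
#' argument is clamped to `>= 1` for numerical stability, so `d = |r1 - r2|`
#' exactly when the angles coincide.
#'
#' @param r1,theta1,r2,theta2 polar coordinates (radii `>= 0`, angles in
#'   radians); vectors are recycled.
#' @param zeta positive curvature constant (default 1).
#' @return nonnegative distances.
#' @export
#' @examples
#' hyperbolic_distance(3, 0, 7, 0)        # same ray: |r1 - r2| = 4
#' hyperbolic_distance(10, 0, 10, pi)     # antipodal points
hyperbolic_distance <- function(r1, theta1, r2, theta2, zeta = 1) {
  if (any(r1 < 0) || any(r2 < 0)) stop("radial coordinates must be >= 0")
  if (zeta <= 0) stop("zeta must be positive")
  dth <- circ_dist(theta1, theta2)
  arg <- cosh(zeta * r1) * cosh(zeta * r2) -
    sinh(zeta * r1) * sinh(zeta * r2) * cos(dth)
  acosh(pmax(arg, 1)) / zeta
}

#' Large-radius approximation to the hyperbolic distance
#'
#' `d ~ r1 + r2 + 2*log(sin(dtheta/2))`, accurate when both radii are large.
#'
#' @inheritParams hyperbolic_distance
#' @return approximate distances.
#' @export
hyperbolic_distance_approx <- function(r1, theta1, r2, theta2) {
  r1 + r2 + 2 * log(sin(circ_dist(theta1, theta2) / 2))
}

#' Fermi connection probability
#'
#' `p = 1 / (1 + exp((beta*zeta/2) * (d - R)))`: a temperature-controlled
#' sigmoid in the hyperbolic distance, equal to 1/2 at `d = R`, strictly
#' decreasing in `d`, and overflow-safe for large `|d - R|`.
#'
#' @param d hyperbolic distance(s).
#' @param R disk radius.
#' @param beta inverse temperature `1/T` (default 10, i.e. `T = 0.1`).
#' @param zeta curvature constant (default 1).
#' @return probabilities in (0, 1).
#' @export
#' @examples
#' connection_probability(5, 5)            # d = R: exactly 0.5
#' connection_probability(5.2, 5)          # 1 / (1 + e)
connection_probability <- function(d, R, beta = 10, zeta = 1) {
  if (beta <= 0 || zeta <= 0) stop("beta and zeta must be positive")
  plogis(-(beta * zeta / 2) * (d - R))
}

#' Radius of the embedding disk
#'
#' `R = 2 * log(V^2 (gamma-1)^2 T / (E sin(pi T) (gamma-2)^2))`: the disk
#' radius that makes the expected number of Fermi-connected pairs match the
#' observed edge count for a scale-free network with exponent `gamma`.
#'
#' @param V number of nodes (`>= 2`).
#' @param E number of edges (`>= 1`).
#' @param gamma power-law exponent, strictly `> 2`.
#' @param temperature temperature `T` in (0, 1), default 0.1.
#' @return the disk radius (finite, increasing in `V` at fixed `E`).
#' @export
disk_radius <- function(V, E, gamma, temperature = 0.1) {
  stopifnot(V >= 2, E >= 1)
  if (gamma <= 2) stop("disk_radius requires gamma > 2")
  if (temperature <= 0 || temperature >= 1) stop("temperature must be in (0, 1)")
  2 * log(V^2 * (gamma - 1)^2 * temperature /
            (E * sin(pi * temperature) * (gamma - 2)^2))
}

#' Radial coordinate of a node from its degree
#'
#' The radius is `min(R, 2 * log(2 V (gamma-1) T / (k sin(pi T) (gamma-2))))`:
#' non-increasing in the degree `k` and capped at the disk radius, so the
#' maximum-degree node sits closest to the disk centre.
#'
#' @param k node degree(s), `>= 1`.  Isolated nodes have no radial coordinate
#'   and must be excluded before embedding.
#' @inheritParams disk_radius
#' @param R disk radius, from [disk_radius()].
#' @return radial coordinate(s) in `[0, R]` (up to the formula's range).
#' @export
radial_coordinate <- function(k, V, gamma, temperature = 0.1, R) {
  if (any(k < 1)) stop("radial_coordinate is undefined for degree 0")
  if (gamma <= 2) stop("radial_coordinate requires gamma > 2")
  pmin(R, 2 * log(2 * V * (gamma - 1) * temperature /
                    (k * sin(pi * temperature) * (gamma - 2))))
}

#' Common-neighbour likelihood estimate of an angular gap
#'
#' Expected absolute angular difference between two nodes with `cn` common
#' neighbours and radial coordinates `ri`, `rj`:
#' `K * cn^(1/(2-gamma)) * exp(-(1/2) * (ri + rj - R) / (2 - 4*gamma))`.
#' For `gamma > 2` the estimate is strictly decreasing in `cn` (more shared
#' neighbours imply angular proximity) and increasing in `ri + rj`
#' (peripheral pairs need a larger angular gap to be equally unlikely
#' neighbours).  The scale constant `K` is calibrated by the embedder so that
#' the globally most-similar pair maps to one angular resolution slot,
#' `2*pi/V`.
#'
#' @param cn number of common neighbours, `>= 1` (pairs without common
#'   neighbours carry no angular information and are skipped).
#' @param ri,rj radial coordinates of the pair.
#' @param gamma power-law exponent `> 2`.
#' @param R disk radius.
#' @param K positive scale constant (default 1, i.e. uncalibrated).
#' @return expected absolute angular gap(s), `> 0`.
#' @export
angular_gap_estimate <- function(cn, ri, rj, gamma, R, K = 1) {
  if (any(cn < 1)) stop("angular_gap_estimate requires cn >= 1")
  if (gamma <= 2) stop("angular_gap_estimate requires gamma > 2")
  K * cn^(1 / (2 - gamma)) * exp(-0.5 * (ri + rj - R) / (2 - 4 * gamma))
}
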