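#' Two-step connectivity score
#'
#' The number of pairs of a node's neighbours that are not directly linked:
#' `choose(k_v, 2)` minus the number of edges among the neighbours (i.e. the
#' open-triad count through the node).  High values flag local bridges.
#'
#' @param net an undirected simple [igraph::graph].
#' @param v node labels (default: all nodes).
#' @return a named integer vector of scores.
#' @export
#' @examples
#' g <- make_network(c("c", "c", "c", "c"), c("a", "b", "d", "e"))
#' two_step_score(g, "c")  # star centre, 4 leaves: choose(4,2) = 6
two_step_score <- function(net, v = igraph::V(net)$name) {
  k <- igraph::degree(net, v)
  tri <- igraph::count_triangles(net, v)
  setNames(as.integer(choose(k, 2) - tri), v)
}

#' Geodesic distance across an angular gap (boundary approximation)
#'
#' Large-radius approximation for two nodes at radius `R0` separated by an
#' angular gap `dtheta`: `d = 2*R0 + 2*log(dtheta/2)`.
#'
#' @param R0 radial coordinate of the two boundary nodes.
#' @param dtheta angular gap in radians.
#' @return approximate hyperbolic distance.
#' @export
boundary_gap_distance <- function(R0, dtheta) {
  2 * R0 + 2 * log(dtheta / 2)
}

#' Fermi probability of a connection across an angular gap
#'
#' Plugs [boundary_gap_distance()] into the Fermi rule:
#' `p = 1 / (1 + exp((beta*zeta/2) * (2*R0 + 2*log(dtheta/2) - R)))`.
#'
#' @inheritParams boundary_gap_distance
#' @param R disk radius.
#' @param beta inverse temperature, default 10.
#' @param zeta curvature constant, default 1.
#' @return the connection probability.
#' @export
boundary_connection_probability <- function(dtheta, R0, R, beta = 10,
                                            zeta = 1) {
  plogis(-(beta * zeta / 2) * (boundary_gap_distance(R0, dtheta) - R))
}

#' Infimum of the spanner angular region
#'
#' The smallest angular gap for which the cross-boundary connection
#' probability does not exceed `a`:
#' `inf = 2 * ((1-a)/a)^(1/(beta*zeta)) * exp(R/2 - R0)`, obtained by
#' inverting [boundary_connection_probability()]; plugging the result back
#' yields exactly `p = a`.
#'
#' @param a maximum tolerated cross-boundary connection probability, in
#'   (0, 1); strictly decreasing in `a`.
#' @param beta inverse temperature, default 10.
#' @param zeta curvature constant, default 1.
#' @param R disk radius.
#' @param R0 minimum candidate radius (radial floor).
#' @return the infimum gap, `> 0`.
#' @export
shs_gap_infimum <- function(a, beta = 10, zeta = 1, R, R0) {
  if (a <= 0 || a >= 1) stop("a must lie strictly in (0, 1)")
  2 * ((1 - a) / a)^(1 / (beta * zeta)) * exp(R / 2 - R0)
}

#' Supremum of the spanner angular region
#'
#' Width left between two adjacent Gaussian communities once each is trimmed
#' at the angular offset where its (single-component) density falls to `p`:
#' `sup = 2*pi/C - 2*sigma*sqrt(-2*log(sqrt(2*pi)*sigma*p))`.
#' As `sigma -> 0` the supremum tends to the full inter-mean spacing
#' `2*pi/C`; it is undefined when the root argument is negative
#' (`sqrt(2*pi)*sigma*p > 1`) or when the trimmed width is nonpositive, in
#' which case callers fall back to the selected critical gap.
#'
#' @param C number of communities.
#' @param sigma angular standard deviation of a community, `> 0`.
#' @param p density/tail level, `> 0` with `sqrt(2*pi)*sigma*p <= 1` (a
#'   density value, so it may exceed 1 for narrow communities); either
#'   supplied directly or derived from the radial tail probability (see
#'   [sdhe_detect()]).
#' @return the supremum gap, `> 0`.
#' @export
shs_gap_supremum <- function(C, sigma, p) {
  if (sigma <= 0) stop("sigma must be positive")
  if (p <= 0) stop("p must be positive")
  arg <- sqrt(2 * pi) * sigma * p
  if (arg > 1) stop("spanner region undefined: sqrt(2*pi)*sigma*p > 1")
  val <- 2 * pi / C - 2 * sigma * sqrt(-2 * log(arg))
  if (val <= 0) stop("spanner region undefined: nonpositive width")
  val
}

#' Radial floor for spanner candidates
#'
#' The radius `R0` such that a fraction `p` of the embedded nodes lies
#' outside it (`P(r > R0) = p`): the type-1 empirical quantile of the radii
#' at level `1 - p`.  Hubs, which sit at small radii, fall below the floor
#' and are excluded as spanner candidates.
#'
#' @param coords a [disk_coordinates()] table (or data frame with column
#'   `r`).
#' @param p tail probability in (0, 1), default 0.9.
#' @return the radial floor `R0`.
#' @export
radial_floor <- function(coords, p = 0.9) {
  if (p <= 0 || p >= 1) stop("p must lie strictly in (0, 1)")
  r <- sort(coords$r)
  # type-1 (inverse-CDF) quantile as an explicit order statistic, immune to
  # floating-point noise in 1 - p
  k <- max(1L, ceiling((1 - p) * length(r) - 1e-9))
  r[k]
}

# analytic radial tail probability P(r > R0) through the fitted power law;
# the printed normalisation chain is ambiguous, so the result is clamped
# into (0, 1) and flagged (the empirical quantile path is the default)
analytic_tail_probability <- function(V, gamma, temperature, b, R0) {
  h <- (b / (gamma - 1)) *
    (2 * V * (gamma - 1) * temperature /
       (sin(pi * temperature) * (gamma - 2)))^(1 - gamma)
  p <- 1 - h * exp((gamma - 1) / 2 * R0)
  if (p <= 0 || p >= 1) {
    warning("analytic tail probability fell outside (0, 1); clamped")
    p <- min(max(p, 1e-6), 1 - 1e-6)
  }
  p
}

# mean within-community circular standard deviation of embedded angles
estimate_community_sigma <- function(coords, membership) {
  th <- setNames(coords$theta, coords$node)
  sds <- vapply(split(names(membership), membership), function(nodes) {
    a <- th[nodes]
    if (length(a) < 2) return(NA_real_)
    mu <- atan2(mean(sin(a)), mean(cos(a)))
    dev <- ((a - mu + pi) %% (2 * pi)) - pi
    sqrt(mean(dev^2))
  }, numeric(1))
  sds <- sds[is.finite(sds) & sds > 0]
  if (!length(sds)) return(NA_real_)
  mean(sds)
}

#' Detect structural hole spanners from an embedded, partitioned network
#'
#' Every consecutive angular gap exceeding the selected critical gap marks a
#' community boundary.  Candidate spanners are the nodes whose angle lies
#' within the spanner region width of either boundary node's angle and whose
#' radius exceeds the radial floor `R0` (so hubs are excluded).  The region
#' width is [shs_gap_supremum()] where defined, computed from the detected
#' community count, the within-community angular spread and the tail
#' probability `p`; when undefined it falls back to the critical gap itself,
#' the only remaining angular scale.  Candidates are ranked by
#' [two_step_score()]; the `k` highest strictly positive scorers are
#' returned (ties break by label).
#'
#' @param net an undirected simple [igraph::graph].
#' @param coords a [disk_coordinates()] table covering `net`.
#' @param assignment a `community_assignment` from [critical_gap_sweep()].
#' @param k number of spanners requested (fewer are returned when fewer
#'   candidates have positive scores).
#' @param a maximum cross-boundary connection probability (region infimum
#'   parameter), default 0.5.
#' @param p radial tail probability, default 0.9.
#' @param sigma within-community angular standard deviation used by the
#'   region supremum; by default estimated from the embedded angles of the
#'   detected communities.
#' @param use_analytic_p if `TRUE`, derive the supremum's tail level from
#'   the fitted power-law coefficients instead of using `p` directly.
#' @param gamma,temperature,zeta embedding parameters; default to the values
#'   stored in `coords`.
#' @return an object of class `shs_result`: a data frame with columns
#'   `rank`, `node`, `score`, `gap_id`, plus a `region` attribute listing
#'   `R0`, the infimum and supremum bounds, the applied width and the
#'   parameters.  An empty result (zero rows) is returned when the
#'   partition has a single community.
#' @export
sdhe_detect <- function(net, coords, assignment, k = 10, a = 0.5, p = 0.9,
                        sigma = NULL, use_analytic_p = FALSE,
                        gamma = NULL, temperature = NULL, zeta = NULL) {
  stopifnot(inherits(assignment, "community_assignment"), k >= 1)
  prm <- attr(coords, "params")
  if (is.null(gamma)) gamma <- prm$gamma
  if (is.null(temperature)) temperature <- if (is.null(prm$temperature)) 0.1 else prm$temperature
  if (is.null(zeta)) zeta <- if (is.null(prm$zeta)) 1 else prm$zeta
  beta <- 1 / temperature
  R <- attr(coords, "R")
  if (is.null(R)) R <- max(coords$r)

  nm <- intersect(igraph::V(net)$name, coords$node)
  th <- setNames(coords$theta, coords$node)[nm]
  rr <- setNames(coords$r, coords$node)[nm]
  n <- length(nm)
  Cdet <- assignment$n_communities

  R0 <- radial_floor(coords, p)
  inf_gap <- shs_gap_infimum(a, beta, zeta, R, R0)
  if (is.null(sigma)) sigma <- estimate_community_sigma(coords, assignment$membership)
  p_sup <- if (use_analytic_p && !is.null(gamma)) {
    bcoef <- (gamma - 1) * max(2, min(igraph::degree(net)))^(gamma - 1)
    analytic_tail_probability(n, gamma, temperature, bcoef, R0)
  } else {
    p
  }
  sup_gap <- if (is.na(sigma)) NULL else {
    tryCatch(shs_gap_supremum(Cdet, sigma, p_sup), error = function(e) NULL)
  }
  fallback <- is.null(sup_gap)
  width <- if (fallback) assignment$gap else sup_gap

  region <- list(R0 = R0, inf_gap = inf_gap,
                 sup_gap = if (fallback) NA_real_ else sup_gap,
                 width = width, fallback = fallback,
                 a = a, p = p, sigma = sigma, C = Cdet, R = R)

  empty <- function() {
    out <- data.frame(rank = integer(0), node = character(0),
                      score = integer(0), gap_id = integer(0),
                      stringsAsFactors = FALSE)
    structure(out, class = c("shs_result", "data.frame"),
              region = region, k = k)
  }
  if (Cdet < 2 || n < 2) return(empty())

  o <- order_c(th, nm)
  sth <- th[o]
  gaps <- c(diff(sth), sth[1] + 2 * pi - sth[n])
  bnd <- which(gaps > assignment$gap)
  if (!length(bnd)) return(empty())

  cand_idx <- integer(0)
  gap_of <- integer(0)
  for (gi in seq_along(bnd)) {
    i <- bnd[gi]
    j <- if (i == n) 1L else i + 1L
    hit <- which((circ_dist(sth, sth[i]) < width |
                    circ_dist(sth, sth[j]) < width) &
                   rr[o] > R0)
    new <- setdiff(hit, cand_idx)
    cand_idx <- c(cand_idx, new)
    gap_of <- c(gap_of, rep(gi, length(new)))
  }
  if (!length(cand_idx)) return(empty())
  cand <- nm[o][cand_idx]
  sc <- two_step_score(net, cand)
  pos <- sc > 0
  cand <- cand[pos]; sc <- sc[pos]; gap_of <- gap_of[pos]
  if (!length(cand)) return(empty())
  oo <- order_c(-sc, cand)
  take <- oo[seq_len(min(k, length(oo)))]
  out <- data.frame(rank = seq_along(take), node = cand[take],
                    score = as.integer(sc[take]), gap_id = gap_of[take],
                    stringsAsFactors = FALSE)
  structure(out, class = c("shs_result", "data.frame"),
            region = region, k = k)
}

#' @export
print.shs_result <- function(x, ...) {
  reg <- attr(x, "region")
  cat(sprintf(
    "Top-%d structural hole spanners (%d found; region width %.4f%s, R0 = %.3f)\n",
    attr(x, "k"), nrow(x), reg$width,
    if (reg$fallback) " [critical-gap fallback]" else "", reg$R0))
  if (nrow(x)) print.data.frame(as.data.frame(x), row.names = FALSE)
  invisible(x)
}
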