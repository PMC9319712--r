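#' Parameters for the nPSO synthetic-network generator
#'
#' The nonuniform popularity-similarity-optimisation (nPSO) model grows a
#' scale-free network node by node on the hyperbolic disk.  Angular
#' coordinates are drawn from a mixture of `communities` equally-weighted
#' Gaussian components whose means are equally spaced on the circle, which
#' plants a ground-truth community structure.
#'
#' @param n number of nodes (`> m`).
#' @param m links added per arriving node (`>= 1`).
#' @param gamma target power-law exponent, `> 2`.  The popularity-fading
#'   exponent is `beta_pf = 1/(gamma - 1)` (distinct from the Fermi inverse
#'   temperature `beta = 1/T`).
#' @param temperature Fermi temperature `T` in (0, 1); default 0.1.
#' @param zeta curvature constant, default 1.
#' @param communities number of Gaussian mixture components `C >= 1`.
#' @param sigma angular standard deviation of each component, in radians.
#'   Default `(2*pi/communities)/6`, which keeps adjacent component means
#'   about six standard deviations apart so planted communities are
#'   well separated.
#' @param seed integer seed; all generator randomness flows from it.
#' @return an object of class `npso_params`.
#' @seealso [npso_generate()], [sample_angles()]
#' @export
npso_params <- function(n, m, gamma = 2.5, temperature = 0.1, zeta = 1,
                        communities = 1, sigma = NULL, seed = 1) {
  if (is.null(sigma)) sigma <- (2 * pi / communities) / 6
  stopifnot(n > m, m >= 1, communities >= 1, sigma > 0, zeta > 0)
  if (gamma <= 2) stop("npso_params requires gamma > 2")
  if (temperature <= 0 || temperature >= 1) {
    stop("temperature must lie strictly in (0, 1)")
  }
  structure(
    list(n = as.integer(n), m = as.integer(m), gamma = gamma,
         temperature = temperature, zeta = zeta,
         communities = as.integer(communities), sigma = sigma,
         mu = wrap_angle(2 * pi * seq_len(communities) / communities),
         seed = as.integer(seed)),
    class = "npso_params"
  )
}

#' @export
print.npso_params <- function(x, ...) {
  cat(sprintf(
    "nPSO parameters: n=%d m=%d gamma=%.3g T=%.3g C=%d sigma=%.4g seed=%d\n",
    x$n, x$m, x$gamma, x$temperature, x$communities, x$sigma, x$seed))
  invisible(x)
}

# mixture components and wrapped angles, drawn from the current RNG stream
sample_angles_impl <- function(params) {
  comp <- sample.int(params$communities, params$n, replace = TRUE)
  theta <- wrap_angle(params$mu[comp] + rnorm(params$n, 0, params$sigma))
  list(theta = theta, community = comp)
}

#' Sample planted angular coordinates from the Gaussian mixture
#'
#' Each node's component is drawn uniformly among the `C` components
#' (equal mixture proportions); its angle is the component mean plus
#' `N(0, sigma^2)` noise, wrapped to `[0, 2*pi)`.  The component id is the
#' ground-truth community label.
#'
#' @param params an [npso_params()] object; `params$seed` seeds the draw.
#' @return a list with numeric `theta` (angles) and integer `community`
#'   (labels in `1..C`), both of length `n`.
#' @export
sample_angles <- function(params) {
  stopifnot(inherits(params, "npso_params"))
  with_seed(params$seed, sample_angles_impl(params))
}

#' Generate an nPSO synthetic scale-free network
#'
#' Nodes arrive at times `t = 1..n`.  Node `t` appears at radius
#' `r_t = 2*log(t)` with its pre-sampled mixture angle; popularity fading
#' moves every earlier node `s` to `r_s(t) = b*r_s + (1-b)*r_t` with fading
#' exponent `b = 1/(gamma-1)`.  The arriving node connects to exactly
#' `min(m, t-1)` distinct existing nodes, sampled without replacement with
#' weights given by the Fermi probability of the current hyperbolic
#' distances, where the time-dependent disk radius `R_t` is set so the
#' expected degree is `2m`.  Consequently the edge count is the exact
#' deterministic identity `E = m*n - m*(m+1)/2` for every seed.
#'
#' RNG consumption order (one stream seeded by `params$seed`): mixture
#' components, then angular noise, then one weighted draw per arriving node
#' with more than `m` predecessors.
#'
#' @param params an [npso_params()] object.
#' @return a list of class `npso_network` with elements
#'   \describe{
#'     \item{network}{the simple undirected [igraph::graph];}
#'     \item{truth}{data frame `node`, `r`, `theta`, `community` with the
#'       final (faded) ground-truth coordinates and planted labels;}
#'     \item{params}{the generating parameters.}
#'   }
#' @export
#' @examples
#' gen <- npso_generate(npso_params(n = 100, m = 3, communities = 4, seed = 7))
#' igraph::ecount(gen$network)  # 3*100 - 3*4/2 = 294
npso_generate <- function(params) {
  stopifnot(inherits(params, "npso_params"))
  n <- params$n; m <- params$m
  bpf <- 1 / (params$gamma - 1)
  tem <- params$temperature; zeta <- params$zeta
  beta <- 1 / tem

  with_seed(params$seed, {
    ang <- sample_angles_impl(params)
    theta <- ang$theta
    r0 <- 2 * log(seq_len(n))          # radius at own arrival time

    edges <- matrix(0L, nrow = m * n, ncol = 2)
    ne <- 0L
    for (t in 2:n) {
      idx <- seq_len(t - 1L)
      if (t - 1L <= m) {
        tgt <- idx
      } else {
        r_cur <- bpf * r0[idx] + (1 - bpf) * r0[t]
        d <- hyperbolic_distance(r_cur, theta[idx], r0[t], theta[t], zeta)
        Rt <- r0[t] - 2 * log(
          2 * tem * (1 - t^(-(1 - bpf))) /
            (sin(pi * tem) * m * (1 - bpf)))
        w <- connection_probability(d, Rt, beta, zeta)
        tgt <- sample(idx, m, prob = pmax(w, 1e-300))
      }
      k <- length(tgt)
      edges[ne + seq_len(k), 1] <- t
      edges[ne + seq_len(k), 2] <- tgt
      ne <- ne + k
    }
    edges <- edges[seq_len(ne), , drop = FALSE]

    lab <- sprintf("v%0*d", nchar(n), seq_len(n))
    net <- make_network(lab[edges[, 1]], lab[edges[, 2]], nodes = lab)
    truth <- data.frame(
      node = lab,
      r = bpf * r0 + (1 - bpf) * r0[n],
      theta = theta,
      community = ang$community,
      stringsAsFactors = FALSE
    )
    structure(list(network = net, truth = truth, params = params),
              class = "npso_network")
  })
}

#' @export
print.npso_network <- function(x, ...) {
  cat(sprintf("nPSO network: V=%d E=%d planted communities=%d\n",
              igraph::vcount(x$network), igraph::ecount(x$network),
              x$params$communities))
  invisible(x)
}

#' Plant degree-2 bridge nodes between adjacent communities
#'
#' Augments a generated nPSO network with `n_bridges` new nodes, each wired
#' to one randomly chosen member of each of two angularly adjacent planted
#' communities.  These are ground-truth structural hole spanners used to
#' benchmark spanner detection.
#'
#' @param gen an `npso_network` from [npso_generate()].
#' @param n_bridges number of bridge nodes to add (default 4).
#' @param seed integer seed for the random wiring.
#' @return a list of class `npso_network` whose `network` contains the extra
#'   nodes, whose `truth` has `NA` coordinates/labels for them, and with an
#'   extra element `bridges` naming the planted spanners.
#' @export
plant_bridges <- function(gen, n_bridges = 4, seed = 1) {
  stopifnot(inherits(gen, "npso_network"), n_bridges >= 1)
  C <- gen$params$communities
  if (C < 2) stop("bridge planting needs at least 2 planted communities")
  with_seed(seed, {
    first <- sample.int(C, n_bridges, replace = n_bridges > C)
    blab <- sprintf("shs%d", seq_len(n_bridges))
    from <- character(0); to <- character(0)
    for (i in seq_len(n_bridges)) {
      ca <- first[i]
      cb <- ca %% C + 1L
      va <- sample(gen$truth$node[gen$truth$community == ca], 1)
      vb <- sample(gen$truth$node[gen$truth$community == cb], 1)
      from <- c(from, blab[i], blab[i])
      to <- c(to, va, vb)
    }
    net <- igraph::add_vertices(gen$network, n_bridges, name = blab)
    net <- igraph::add_edges(net, rbind(from, to))
    truth <- rbind(gen$truth,
                   data.frame(node = blab, r = NA_real_, theta = NA_real_,
                              community = NA_integer_,
                              stringsAsFactors = FALSE))
    structure(list(network = net, truth = truth, params = gen$params,
                   bridges = blab),
              class = "npso_network")
  })
}
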