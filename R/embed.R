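#' Construct a disk-coordinates table
#'
#' @param node character node labels.
#' @param r radial coordinates (`>= 0`).
#' @param theta angular coordinates, wrapped to `[0, 2*pi)`.
#' @param R disk radius (stored as an attribute).
#' @param params optional list of embedding parameters (gamma, temperature,
#'   zeta, beta, K) stored as an attribute.
#' @return a data frame of class `disk_coordinates` with columns `node`,
#'   `r`, `theta` and attributes `R` and `params`.
#' @export
disk_coordinates <- function(node, r, theta, R = max(r), params = list()) {
  stopifnot(length(node) == length(r), length(r) == length(theta),
            all(r >= 0))
  out <- data.frame(node = as.character(node), r = as.numeric(r),
                    theta = wrap_angle(as.numeric(theta)),
                    stringsAsFactors = FALSE)
  class(out) <- c("disk_coordinates", "data.frame")
  attr(out, "R") <- R
  attr(out, "params") <- params
  out
}

#' @export
print.disk_coordinates <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("Disk coordinates for %d nodes (R = %.4f%s)\n", nrow(x),
              attr(x, "R"),
              if (!is.null(p$gamma))
                sprintf(", gamma = %.3f, T = %.3g", p$gamma, p$temperature)
              else ""))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("... (", nrow(x) - 6, " more rows)\n", sep = "")
  invisible(x)
}

# resolve the exponent used for embedding; falls back to a generic scale-free
# value when the degree tail is too short to fit.  kmin is the modal degree
# (at least 2): the onset of the power-law tail, robust to a handful of
# below-tail nodes that would otherwise drag the MLE below 2.
resolve_gamma <- function(k, gamma) {
  if (is.numeric(gamma)) {
    if (gamma <= 2) stop("embedding requires gamma > 2")
    return(gamma)
  }
  tab <- table(k)
  kmode <- as.integer(names(tab)[which.max(tab)])
  kmin <- max(2, kmode)
  est <- tryCatch(estimate_gamma(k, kmin = kmin)$gamma, error = function(e) NA)
  if (is.na(est)) {
    warning("degree tail too short for gamma estimation; using gamma = 2.5")
    return(2.5)
  }
  if (est <= 2.05) {
    warning(sprintf(
      "estimated gamma = %.3f is at or below the embeddable range; clamped to 2.1",
      est))
    return(2.1)
  }
  est
}

#' Embed a network on the Poincare disk (common-neighbour likelihood method)
#'
#' Radial coordinates come from degrees via [radial_coordinate()]; angular
#' coordinates are obtained in two phases driven by common neighbours.
#'
#' *Initial ordering.*  With the default `init = "agglomerative"`, nodes are
#' ordered around the circle by the leaf order of an average-linkage
#' hierarchical clustering of the cosine dissimilarity
#' `1 - c_ij / sqrt(k_i k_j)` of their neighbourhoods, and spaced uniformly.
#' Nodes sharing many neighbours relative to their degrees thus start out
#' angularly adjacent, and similarity clusters start out as contiguous arcs.
#' `init = "sequential"` instead places nodes one by one in decreasing
#' degree order: each node collects angular-gap estimates
#' ([angular_gap_estimate()]) to the already-placed nodes sharing at least
#' one common neighbour (capped at the `max_refs` largest counts), each
#' estimate proposes placements at plus/minus the gap around the reference,
#' and the candidate maximising the Bernoulli log-likelihood of the observed
#' adjacencies under the Fermi probability over the placed nodes is kept.
#' The sequential variant is retained for auditability; hub-to-hub edges
#' barely constrain angles (their connection reach exceeds the half-circle),
#' so it tends to superpose the high-degree cores of distinct communities
#' and the agglomerative start is the default.
#'
#' *Likelihood sweeps.*  `sweeps` coordinate-wise passes (decreasing degree
#' order) then re-optimise every angle: candidates are the gap estimates
#' around the `max_refs` strongest common-neighbour references plus a coarse
#' uniform grid, scored by the Bernoulli log-likelihood over all other
#' nodes, and the winner is polished by a continuous one-dimensional
#' likelihood maximisation around it (so the fine angular structure is not
#' quantised to the candidate grid).  The gap scale `K` is calibrated so the
#' pair with the globally largest common-neighbour count is assigned one
#' angular resolution slot, `2*pi/V`.
#'
#' @param net a connected simple undirected [igraph::graph] with `V >= 3`.
#'   Disconnected input is reduced to its largest connected component with a
#'   warning; isolated nodes are never embedded.
#' @param gamma power-law exponent used for the radial map; `"auto"`
#'   (default) estimates it from the degree sequence via [estimate_gamma()]
#'   with `kmin` equal to the smallest degree (at least 2).
#' @param temperature Fermi temperature `T`, default 0.1.
#' @param zeta curvature constant, default 1.
#' @param seed integer seed for the jitter fallbacks of the sequential
#'   start; the embedding is deterministic given the input and the seed.
#' @param sweeps number of coordinate-wise likelihood sweeps, default 1.
#' @param init initial angular ordering, `"agglomerative"` (default) or
#'   `"sequential"` (see Details).
#' @param max_refs number of reference nodes (largest common-neighbour
#'   counts) used per placement, default 20.
#' @param grid_n number of coarse grid candidates per sweep, default 64.
#' @return a [disk_coordinates()] table for the embedded nodes, with the
#'   disk radius `R` and the resolved parameters as attributes.
#' @export
#' @examples
#' gen <- npso_generate(npso_params(n = 120, m = 4, communities = 3, seed = 1))
#' coords <- ee_embed(gen$network, seed = 1)
#' head(coords)
ee_embed <- function(net, gamma = "auto", temperature = 0.1, zeta = 1,
                     seed = 1, sweeps = 1,
                     init = c("agglomerative", "sequential"),
                     max_refs = 20, grid_n = 64) {
  init <- match.arg(init)
  stopifnot(igraph::is_igraph(net))
  comp <- igraph::components(net)
  if (comp$no > 1) {
    warning("network is disconnected; embedding the largest connected ",
            "component (", max(comp$csize), " of ", igraph::vcount(net),
            " nodes)")
    big <- which.max(comp$csize)
    net <- igraph::induced_subgraph(net, which(comp$membership == big))
  }
  V <- igraph::vcount(net)
  if (V < 3) stop("embedding requires at least 3 nodes")
  E <- igraph::ecount(net)
  nm <- igraph::V(net)$name
  k <- igraph::degree(net)

  gamma <- resolve_gamma(k, gamma)
  beta <- 1 / temperature
  R <- disk_radius(V, E, gamma, temperature)
  r <- radial_coordinate(k, V, gamma, temperature, R)

  A <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  CN <- Matrix::crossprod(A)               # common-neighbour counts

  # K calibration: most-similar pair maps to one resolution slot 2*pi/V
  TCN <- methods::as(methods::as(CN, "generalMatrix"), "TsparseMatrix")
  off <- TCN@i != TCN@j
  if (any(off) && max(TCN@x[off]) >= 1) {
    cmax <- max(TCN@x[off])
    hit <- which(off & TCN@x == cmax)
    # deterministic tie-break: smallest (label, label) pair in C byte order
    pi_ <- TCN@i[hit] + 1L
    pj_ <- TCN@j[hit] + 1L
    keykey <- paste(pmin(nm[pi_], nm[pj_]), pmax(nm[pi_], nm[pj_]), sep = "\r")
    best <- order_c(keykey)[1]
    K <- (2 * pi / V) /
      angular_gap_estimate(cmax, r[pi_[best]], r[pj_[best]], gamma, R, K = 1)
  } else {
    warning("no pair shares a common neighbour; using uncalibrated K = 1")
    K <- 1
  }

  ord <- order_c(-k, nm)
  theta <- rep(NA_real_, V)
  grid <- seq(0, 2 * pi, length.out = grid_n + 1)[-(grid_n + 1)]
  grid_w <- 2 * pi / grid_n

  # candidate angles for node i against a pool of positioned nodes:
  # gap estimates around the strongest common-neighbour references plus
  # (when with_grid) the coarse uniform grid
  candidates_for <- function(i, pool, theta, with_grid) {
    cn <- CN[, i][pool]
    sel <- cn > 0
    refs <- pool[sel]
    if (length(refs)) {
      cnr <- cn[sel]
      o <- order_c(-cnr, nm[refs])
      take <- o[seq_len(min(max_refs, length(o)))]
      refs <- refs[take]; cnr <- cnr[take]
      gaps <- angular_gap_estimate(cnr, r[i], r[refs], gamma, R, K)
      cand <- as.vector(rbind(theta[refs] + gaps, theta[refs] - gaps))
      wrap_angle(if (with_grid) c(cand, grid) else cand)
    } else if (with_grid) {
      grid
    } else {
      numeric(0)
    }
  }

  score_pick <- function(i, pool, theta, cand, polish) {
    adj01 <- as.integer(A[, i][pool] > 0)
    ll <- placement_loglik(cand, r[i], theta[pool], r[pool], adj01,
                           beta, zeta, R)
    best <- cand[which.max(ll)]
    if (polish) {
      opt <- optimize(function(x) {
        placement_loglik(wrap_angle(x), r[i], theta[pool], r[pool], adj01,
                         beta, zeta, R)
      }, interval = c(best - grid_w, best + grid_w), maximum = TRUE,
      tol = 1e-6)
      best <- wrap_angle(opt$maximum)
    }
    best
  }

  with_seed(seed, {
    if (init == "agglomerative") {
      S <- as.matrix(CN) / sqrt(outer(k, k))
      D <- 1 - S
      diag(D) <- 0
      hc <- stats::hclust(stats::as.dist(D), method = "average")
      theta[hc$order] <- 2 * pi * (seq_len(V) - 1) / V
    } else {
      theta[ord[1]] <- 0
      for (pos in 2:V) {
        i <- ord[pos]
        pool <- ord[seq_len(pos - 1)]
        cand <- candidates_for(i, pool, theta, with_grid = FALSE)
        if (length(cand)) {
          theta[i] <- score_pick(i, pool, theta, cand, polish = FALSE)
        } else {
          nb <- pool[A[, i][pool] > 0]
          theta[i] <- if (length(nb)) {
            ref <- nb[order_c(-k[nb], nm[nb])[1]]
            wrap_angle(theta[ref] + runif(1, 0, 2 * pi / V))
          } else {
            runif(1, 0, 2 * pi)
          }
        }
      }
    }
    for (sweep in seq_len(sweeps)) {
      for (pos in seq_len(V)) {
        i <- ord[pos]
        pool <- setdiff(seq_len(V), i)
        cand <- candidates_for(i, pool, theta, with_grid = TRUE)
        theta[i] <- score_pick(i, pool, theta, cand, polish = TRUE)
      }
    }
  })

  disk_coordinates(nm, r, theta, R = R,
                   params = list(gamma = gamma, temperature = temperature,
                                 zeta = zeta, beta = beta, K = K))
}

#' Read node coordinates from a TSV file
#'
#' Columns `node`, `r`, `theta`; the disk radius may be given on a comment
#' line `# R = <value>` (as written by [write_coordinates()]).
#'
#' @param path input file path.
#' @return a [disk_coordinates()] table.
#' @export
read_coordinates <- function(path) {
  first <- readLines(path, n = 1)
  R <- if (grepl("^#\\s*R\\s*=", first)) {
    as.numeric(sub("^#\\s*R\\s*=\\s*", "", first))
  } else NA_real_
  df <- read.table(path, header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE)
  stopifnot(all(c("node", "r", "theta") %in% names(df)))
  disk_coordinates(df$node, df$r, df$theta,
                   R = if (is.na(R)) max(df$r) else R)
}

#' Write node coordinates to a TSV file
#'
#' @param coords a [disk_coordinates()] table.
#' @param path output file path.
#' @export
write_coordinates <- function(coords, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# R = %.17g", attr(coords, "R")), con)
  write.table(as.data.frame(coords)[, c("node", "r", "theta")], con,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
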