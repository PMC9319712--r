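#' Tie strength of an edge
#'
#' `w_ij = c_ij / (k_i + k_j - 2 - c_ij)` with `c_ij` the number of common
#' neighbours: the fraction of the pair's other contacts that are shared.
#' Symmetric; 0 when the endpoints share no neighbour (a weak tie).  For an
#' isolated dyad the denominator vanishes and the strength is defined as 0.
#'
#' @param net an undirected simple [igraph::graph].
#' @param i,j node labels of an edge of `net`.
#' @return the tie strength, `>= 0`.
#' @export
#' @examples
#' tri <- make_network(c("a", "b", "c"), c("b", "c", "a"))
#' tie_strength(tri, "a", "b")  # 1 / (2 + 2 - 2 - 1) = 1
tie_strength <- function(net, i, j) {
  if (!igraph::are_adjacent(net, i, j)) stop("(", i, ", ", j, ") is not an edge")
  ni <- igraph::neighbors(net, i)$name
  nj <- igraph::neighbors(net, j)$name
  cij <- length(intersect(ni, nj))
  denom <- length(ni) + length(nj) - 2 - cij
  if (denom <= 0) {
    message("tie_strength: degenerate dyad (", i, ", ", j, "); returning 0")
    return(0)
  }
  cij / denom
}

#' Average connection strength of a node
#'
#' `w_i = (1 / Cnb(i)) * sum_j w_ij`, the sum of the tie strengths of the
#' node's incident edges divided by the number of distinct communities its
#' neighbours belong to (not by its degree), so a node whose neighbours all
#' share one community can score above the largest single tie strength.
#' Small values flag likely structural hole spanners.
#'
#' @param net an undirected simple [igraph::graph].
#' @param membership community labels named by node, covering the
#'   neighbours of `v`.
#' @param v a node label with at least one neighbour.
#' @return the average connection strength.
#' @export
avg_connection_strength <- function(net, membership, v) {
  nb <- igraph::neighbors(net, v)$name
  if (!length(nb)) stop("average connection strength is undefined for isolated node ", v)
  w <- vapply(nb, function(j) tie_strength(net, v, j), numeric(1))
  cnb <- length(unique(membership[nb]))
  sum(w) / cnb
}

#' CS-score: joint community/spanner quality
#'
#' `CS = Q / mean(strengths)`: the modularity of the detected partition
#' divided by the mean average-connection-strength of the selected top-k
#' spanners.  Low spanner strengths (genuinely weak ties) inflate the score,
#' so higher is better.  A zero mean strength yields `Inf` with attribute
#' `flagged = TRUE`.
#'
#' @param Q modularity of the partition.
#' @param strengths numeric vector of the k selected nodes' average
#'   connection strengths.
#' @return the CS-score (possibly a flagged `Inf` sentinel).
#' @export
cs_score <- function(Q, strengths) {
  stopifnot(length(strengths) >= 1)
  ms <- mean(strengths)
  if (ms == 0) {
    return(structure(Inf, flagged = TRUE))
  }
  Q / ms
}

#' Intra- and inter-subgraph density
#'
#' For a node set `g` of size `Vg` inside a network with `V` nodes:
#' `rho_intra = (# internal edges) / (Vg*(Vg-1)/2)` and
#' `rho_inter = (# boundary edges) / (Vg*(V-Vg))`.  A community has a large
#' intra- and a small inter-density.
#'
#' @param net an undirected simple [igraph::graph].
#' @param nodeset character vector of node labels, with
#'   `1 < length(nodeset) < V`.
#' @return a list with `rho_intra` and `rho_inter`.
#' @export
subgraph_densities <- function(net, nodeset) {
  V <- igraph::vcount(net)
  Vg <- length(nodeset)
  if (Vg <= 1 || Vg >= V) stop("nodeset must satisfy 1 < |g| < V")
  internal <- igraph::ecount(igraph::induced_subgraph(net, nodeset))
  inc <- sum(igraph::degree(net, nodeset))
  boundary <- inc - 2 * internal
  list(rho_intra = internal / (Vg * (Vg - 1) / 2),
       rho_inter = boundary / (Vg * (V - Vg)))
}

#' Baseline top-k spanner rankings
#'
#' Standard whole-network rankings used for comparison: PageRank (damping
#' 0.85), exact shortest-path betweenness, or the global two-step
#' connectivity score.  Ties break by node label.
#'
#' @param net a connected undirected [igraph::graph].
#' @param method one of `"pagerank"`, `"betweenness"`, `"two_step"`.
#' @param k number of nodes returned.
#' @return a character vector of the top-k node labels.
#' @export
baseline_topk <- function(net, method = c("pagerank", "betweenness",
                                          "two_step"), k) {
  method <- match.arg(method)
  nm <- igraph::V(net)$name
  score <- switch(method,
    pagerank = igraph::page_rank(net, damping = 0.85)$vector,
    betweenness = igraph::betweenness(net),
    two_step = two_step_score(net)
  )
  # round away solver noise so analytically tied scores break by label
  score <- signif(score, 10)
  nm[order_c(-score, nm)][seq_len(min(k, length(nm)))]
}

#' Evaluate spanner-detection methods on one network
#'
#' For each method's top-k node set, reports the mean average-connection
#' strength (lower is a better spanner set) and the CS-score (modularity
#' over mean strength; higher is better).
#'
#' @param net an undirected simple [igraph::graph].
#' @param coords a [disk_coordinates()] table (needed for `"sdhe"`).
#' @param assignment a `community_assignment` from [critical_gap_sweep()];
#'   supplies both the community labels and `Q`.
#' @param methods character vector among `"sdhe"`, `"pagerank"`,
#'   `"betweenness"`, `"two_step"`.
#' @param k top-k size, default 10 (always reported in the output).
#' @param a,p spanner-region parameters forwarded to [sdhe_detect()].
#' @param ... further arguments passed to [sdhe_detect()].
#' @return a data frame of class `evaluation_report` with one row per
#'   method: `method`, `k`, `n_selected`, `mean_strength`, `Q`, `cs_score`.
#' @export
evaluate_methods <- function(net, coords, assignment,
                             methods = c("sdhe", "pagerank", "betweenness",
                                         "two_step"),
                             k = 10, a = 0.5, p = 0.9, ...) {
  stopifnot(inherits(assignment, "community_assignment"), k >= 1)
  memb <- assignment$membership
  rows <- lapply(methods, function(mt) {
    sel <- if (mt == "sdhe") {
      sdhe_detect(net, coords, assignment, k = k, a = a, p = p, ...)$node
    } else {
      baseline_topk(net, mt, k)
    }
    if (!length(sel)) {
      return(data.frame(method = mt, k = k, n_selected = 0L,
                        mean_strength = NA_real_, Q = assignment$Q,
                        cs_score = NA_real_, stringsAsFactors = FALSE))
    }
    w <- vapply(sel, function(v) avg_connection_strength(net, memb, v),
                numeric(1))
    cs <- cs_score(assignment$Q, w)
    data.frame(method = mt, k = k, n_selected = length(sel),
               mean_strength = mean(w), Q = assignment$Q,
               cs_score = as.numeric(cs), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("evaluation_report", "data.frame")
  out
}
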