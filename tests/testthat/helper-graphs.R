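# small graph builders and independent brute-force oracles used across tests

triangle_graph <- function(labels = c("a", "b", "c")) {
  make_network(labels[c(1, 2, 3)], labels[c(2, 3, 1)])
}

star_graph <- function(n_leaves = 5) {
  make_network(rep("c", n_leaves), paste0("l", seq_len(n_leaves)))
}

# two triangles whose apexes are joined by one direct edge
two_triangles_bridge <- function() {
  make_network(c("a1", "a2", "a3", "b1", "b2", "b3", "a1"),
               c("a2", "a3", "a1", "b2", "b3", "b1", "b1"))
}

# two triangles joined through a degree-2 bridge NODE
two_triangles_bridge_node <- function() {
  make_network(c("a1", "a2", "a3", "b1", "b2", "b3", "x", "x"),
               c("a2", "a3", "a1", "b2", "b3", "b1", "a1", "b1"))
}

# two K6 cliques joined through a degree-2 bridge node
barbell_bridge_node <- function() {
  a <- paste0("a", 1:6)
  b <- paste0("b", 1:6)
  ea <- t(combn(a, 2)); eb <- t(combn(b, 2))
  make_network(c(ea[, 1], eb[, 1], "x", "x"),
               c(ea[, 2], eb[, 2], "a1", "b1"))
}

# two K6 cliques joined by one direct edge a1-b1
barbell_direct <- function() {
  a <- paste0("a", 1:6)
  b <- paste0("b", 1:6)
  ea <- t(combn(a, 2)); eb <- t(combn(b, 2))
  make_network(c(ea[, 1], eb[, 1], "a1"),
               c(ea[, 2], eb[, 2], "b1"))
}

# Erdos-Renyi graph with string labels and at least one edge
random_graph <- function(n, p, seed) {
  g <- withr::with_seed(seed, igraph::sample_gnp(n, p))
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  if (igraph::ecount(g) == 0) {
    g <- igraph::add_edges(g, c("n01", "n02"))
  }
  g
}

random_membership <- function(net, k, seed) {
  withr::with_seed(seed,
    setNames(sample.int(k, igraph::vcount(net), replace = TRUE),
             igraph::V(net)$name))
}

# O(V^2) modularity oracle: direct double sum over ordered node pairs
oracle_modularity <- function(net, membership) {
  nm <- igraph::V(net)$name
  m <- membership[nm]
  A <- as.matrix(igraph::as_adjacency_matrix(net))
  k <- igraph::degree(net)
  E <- igraph::ecount(net)
  tot <- 0
  for (i in seq_along(nm)) {
    for (j in seq_along(nm)) {
      if (m[i] == m[j]) tot <- tot + A[i, j] - k[i] * k[j] / (2 * E)
    }
  }
  unname(tot / (2 * E))
}

# brute-force two-step oracle: enumerate neighbour pairs
oracle_two_step <- function(net, v) {
  nb <- igraph::neighbors(net, v)$name
  if (length(nb) < 2) return(0L)
  prs <- combn(nb, 2)
  sum(!apply(prs, 2, function(p) igraph::are_adjacent(net, p[1], p[2])))
}

# NMI between a detected assignment and planted labels (NA truth dropped)
planted_nmi <- function(assignment, truth) {
  keep <- names(assignment$membership)[!is.na(truth[names(assignment$membership)])]
  igraph::compare(as.integer(factor(truth[keep])),
                  as.integer(factor(assignment$membership[keep])),
                  method = "nmi")
}

# signed smallest-arc difference
circ_signed <- function(a, b) ((a - b + pi) %% (2 * pi)) - pi

# unsigned circle distance
circ_dist <- function(a, b) {
  d <- abs(a - b) %% (2 * pi)
  pmin(d, 2 * pi - d)
}
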