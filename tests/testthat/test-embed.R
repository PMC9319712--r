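test_that("disk radius follows its closed form and scaling identities", {
  V <- 2000; E <- 98725; g <- 2.9; tem <- 0.1
  R <- disk_radius(V, E, g, tem)
  # independent evaluation through the expanded log identity
  R2 <- 2 * (2 * log(V) + 2 * log(g - 1) + log(tem) -
               log(E) - log(sin(pi * tem)) - 2 * log(g - 2))
  expect_equal(R, R2, tolerance = 1e-12)
  expect_equal(disk_radius(2 * V, E, g, tem) - R, 4 * log(2),
               tolerance = 1e-12)
  E0 <- V^2 * (g - 1)^2 * tem / (sin(pi * tem) * (g - 2)^2)
  expect_equal(disk_radius(V, E0, g, tem), 0, tolerance = 1e-9)
  expect_error(disk_radius(V, E, 2, tem), "gamma > 2")
})

test_that("radial coordinates decrease with degree and cap at R", {
  V <- 2000; g <- 2.9; tem <- 0.1
  R <- disk_radius(V, 98725, g, tem)
  r_big <- radial_coordinate(99, V, g, tem, R)
  expect_lt(r_big, R)
  expect_equal(r_big,
               2 * log(2 * V * (g - 1) * tem / (99 * sin(pi * tem) * (g - 2))))
  # low degree in a small disk hits the cap
  R_small <- disk_radius(20, 80, 2.5, tem)
  expect_equal(radial_coordinate(1, 20, 2.5, tem, R_small), R_small)
  expect_lt(radial_coordinate(99, V, g, tem, R),
            radial_coordinate(3, V, g, tem, R))
  expect_error(radial_coordinate(0, V, g, tem, R), "degree 0")
})

test_that("common-neighbour gap estimates scale as the parsed power law", {
  g <- 2.9; R <- 10
  e1 <- angular_gap_estimate(4, 5, 6, g, R)
  e2 <- angular_gap_estimate(8, 5, 6, g, R)
  expect_equal(e2 / e1, 2^(1 / (2 - g)), tolerance = 1e-12)
  expect_lt(e2, e1)  # more common neighbours, smaller gap
  # the radial coefficient -1/2 / (2 - 4*gamma) is positive for gamma > 2,
  # so equal-cn pairs with larger radii get larger estimates under this parse
  expect_gt(angular_gap_estimate(4, 8, 8, g, R),
            angular_gap_estimate(4, 5, 6, g, R))
  expect_error(angular_gap_estimate(0, 5, 6, g, R), "cn >= 1")
})

test_that("the embedder calibrates K so the most similar pair spans one slot", {
  gen <- npso_generate(npso_params(150, 4, communities = 3, seed = 4))
  co <- ee_embed(gen$network, seed = 1)
  prm <- attr(co, "params")
  A <- igraph::as_adjacency_matrix(gen$network, sparse = TRUE)
  CN <- as.matrix(Matrix::crossprod(A))
  diag(CN) <- 0
  cmax <- max(CN)
  hit <- which(CN == cmax, arr.ind = TRUE)[1, ]
  r <- setNames(co$r, co$node)[igraph::V(gen$network)$name]
  est <- angular_gap_estimate(cmax, r[hit[1]], r[hit[2]], prm$gamma,
                              attr(co, "R"), prm$K)
  expect_equal(unname(est), 2 * pi / igraph::vcount(gen$network),
               tolerance = 1e-10)
})

test_that("degree-driven radii: equal degrees tie and hubs sit innermost", {
  co3 <- ee_embed(triangle_graph(), gamma = 2.5, seed = 1)
  expect_equal(length(unique(round(co3$r, 12))), 1)
  expect_warning(co_star <- ee_embed(star_graph(5), seed = 1),
                 "gamma")
  r <- setNames(co_star$r, co_star$node)
  expect_true(all(r["c"] < r[paste0("l", 1:5)]))
})

test_that("clique pairs separate angularly across the joining edge", {
  net <- barbell_direct()
  co <- ee_embed(net, gamma = 2.5, seed = 1)
  th <- setNames(co$theta, co$node)
  a <- paste0("a", 2:6); b <- paste0("b", 2:6)  # non-bridge nodes
  within <- c(apply(combn(a, 2), 2, function(p) circ_dist(th[p[1]], th[p[2]])),
              apply(combn(b, 2), 2, function(p) circ_dist(th[p[1]], th[p[2]])))
  cross <- as.vector(outer(a, b, function(x, y) circ_dist(th[x], th[y])))
  expect_lt(max(within), min(cross))
})

test_that("embedded edges carry larger Fermi probabilities than non-edges", {
  gen <- npso_generate(npso_params(500, 4, gamma = 2.7, communities = 4,
                                   seed = 8))
  net <- gen$network
  co <- ee_embed(net, seed = 1)
  prm <- attr(co, "params")
  th <- setNames(co$theta, co$node); r <- setNames(co$r, co$node)
  el <- igraph::as_edgelist(net)
  p_edge <- connection_probability(
    hyperbolic_distance(r[el[, 1]], th[el[, 1]], r[el[, 2]], th[el[, 2]]),
    attr(co, "R"), prm$beta)
  non <- withr::with_seed(1, {
    nm <- igraph::V(net)$name
    out <- matrix(nm[sample.int(length(nm), 2 * nrow(el) * 2, replace = TRUE)],
                  ncol = 2)
    out <- out[out[, 1] != out[, 2], , drop = FALSE]
    adj <- mapply(function(x, y) igraph::are_adjacent(net, x, y),
                  out[, 1], out[, 2])
    out[!adj, , drop = FALSE][seq_len(nrow(el)), ]
  })
  p_non <- connection_probability(
    hyperbolic_distance(r[non[, 1]], th[non[, 1]], r[non[, 2]], th[non[, 2]]),
    attr(co, "R"), prm$beta)
  expect_gt(mean(p_edge), mean(p_non))
})

test_that("embedded angular proximity recovers planted co-membership", {
  # same-community pairs sit angularly closer than different-community
  # pairs: concordance probability P(d_same < d_diff) over sampled pairs
  # (within-arc node order and the cyclic arrangement of well-separated
  # communities are not identifiable from the graph, so proximity, not
  # pairwise order, is the recoverable signal)
  auc <- sapply(1:5, function(s) {
    gen <- npso_generate(npso_params(500, 6, gamma = 2.7, communities = 4,
                                     sigma = (2 * pi / 4) / 8, seed = s))
    co <- ee_embed(gen$network, seed = s)
    th <- setNames(co$theta, co$node)
    cm <- setNames(gen$truth$community, gen$truth$node)
    prs <- withr::with_seed(s, {
      nodes <- names(th)
      i <- sample(nodes, 8000, replace = TRUE)
      j <- sample(nodes, 8000, replace = TRUE)
      cbind(i, j)[i != j, ]
    })
    d <- circ_dist(th[prs[, 1]], th[prs[, 2]])
    same <- cm[prs[, 1]] == cm[prs[, 2]]
    d_diff <- withr::with_seed(s, sample(d[!same], 2000))
    mean(outer(d[same], d_diff, "<"))
  })
  expect_gt(median(auc), 0.8)
})

test_that("embedding is deterministic and guards its preconditions", {
  gen <- npso_generate(npso_params(120, 4, communities = 3, seed = 6))
  co1 <- ee_embed(gen$network, seed = 3)
  co2 <- ee_embed(gen$network, seed = 3)
  expect_identical(co1, co2)

  disc <- igraph::disjoint_union(
    igraph::make_full_graph(5), igraph::make_full_graph(4))
  igraph::V(disc)$name <- paste0("v", 1:9)
  expect_warning(cod <- ee_embed(disc, gamma = 2.5, seed = 1), "disconnected")
  expect_equal(nrow(cod), 5)
  expect_error(ee_embed(make_network("a", "b"), gamma = 2.5), "at least 3")
})

test_that("coordinate files round-trip with the disk radius header", {
  gen <- npso_generate(npso_params(60, 3, communities = 2, seed = 2))
  co <- ee_embed(gen$network, seed = 1)
  f <- withr::local_tempfile()
  write_coordinates(co, f)
  back <- read_coordinates(f)
  expect_equal(attr(back, "R"), attr(co, "R"))
  expect_equal(back$theta, co$theta, tolerance = 1e-12)
  expect_identical(back$node, co$node)
})
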