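test_that("modularity reproduces hand-computable partitions", {
  net <- two_triangles_bridge()
  all_one <- setNames(rep(1, 7), igraph::V(net)$name)
  expect_equal(modularity_q(net, all_one), 0)
  split2 <- setNames(ifelse(grepl("^a", igraph::V(net)$name), 1, 2),
                     igraph::V(net)$name)
  expect_equal(modularity_q(net, split2), 5 / 14, tolerance = 1e-12)
  dyads <- make_network(c("a", "c"), c("b", "d"))
  comp <- setNames(c(1, 1, 2, 2), c("a", "b", "c", "d"))
  expect_equal(modularity_q(dyads, comp), 1 / 2, tolerance = 1e-12)
  expect_error(modularity_q(make_network(character(0), character(0),
                                         nodes = c("a", "b")), c(a = 1, b = 1)),
               "without edges")
})

test_that("modularity agrees with the brute-force pairwise oracle", {
  for (s in 1:10) {
    net <- random_graph(18, 0.2, seed = s)
    memb <- random_membership(net, 3, seed = s + 100)
    expect_lt(abs(modularity_q(net, memb) - oracle_modularity(net, memb)),
              1e-12)
  }
})

test_that("the node-normalised audit variant differs from standard modularity", {
  net <- two_triangles_bridge()
  memb <- setNames(ifelse(grepl("^a", igraph::V(net)$name), 1, 2),
                   igraph::V(net)$name)
  V <- igraph::vcount(net)
  A <- as.matrix(igraph::as_adjacency_matrix(net))
  k <- igraph::degree(net)
  direct <- 0
  for (i in seq_len(V)) for (j in seq_len(V)) {
    s <- if (memb[i] == memb[j]) 1 else -1
    direct <- direct + (A[i, j] - k[i] * k[j] / (2 * V)) * (s + 1)
  }
  direct <- unname(direct / (4 * V))
  expect_equal(modularity_printed(net, memb), direct, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(modularity_printed(net, memb),
                                modularity_q(net, memb))))
})

test_that("the critical-gap sweep recovers angular clusters", {
  # nodes at {0, 0.1, pi, pi+0.1}; edges inside the two close pairs
  net <- make_network(c("u1", "u3"), c("u2", "u4"))
  co <- disk_coordinates(c("u1", "u2", "u3", "u4"), rep(1, 4),
                         c(0, 0.1, pi, pi + 0.1))
  asg <- critical_gap_sweep(net, co)
  expect_equal(asg$n_communities, 2)
  expect_equal(asg$Q, 1 / 2, tolerance = 1e-12)
  expect_equal(unname(asg$membership["u1"]), unname(asg$membership["u2"]))
  expect_equal(unname(asg$membership["u3"]), unname(asg$membership["u4"]))

  # complete graph, equally spaced: any cut lowers Q below 0
  k6 <- igraph::make_full_graph(6)
  igraph::V(k6)$name <- paste0("v", 1:6)
  co6 <- disk_coordinates(paste0("v", 1:6), rep(1, 6), 2 * pi * (0:5) / 6)
  asg6 <- critical_gap_sweep(k6, co6)
  expect_equal(asg6$n_communities, 1)
  expect_equal(asg6$Q, 0)

  # rotation invariance
  co_rot <- disk_coordinates(c("u1", "u2", "u3", "u4"), rep(1, 4),
                             c(0, 0.1, pi, pi + 0.1) + 1.234)
  asg_rot <- critical_gap_sweep(net, co_rot)
  expect_equal(asg_rot$Q, asg$Q)
  expect_identical(unname(asg_rot$membership[c("u1", "u2", "u3", "u4")] ==
                            asg_rot$membership["u1"]),
                   unname(asg$membership[c("u1", "u2", "u3", "u4")] ==
                            asg$membership["u1"]))
})

test_that("every detected community is a contiguous angular arc", {
  for (s in 1:8) {
    net <- random_graph(25, 0.15, seed = s)
    th <- withr::with_seed(s + 50, runif(25, 0, 2 * pi))
    co <- disk_coordinates(igraph::V(net)$name, rep(1, 25), th)
    asg <- critical_gap_sweep(net, co)
    o <- order(co$theta)
    runs <- rle(as.integer(asg$membership[co$node[o]]))$values
    # circular contiguity: each label appears in exactly one run once the
    # wrap-around join is merged
    if (length(runs) > 1 && runs[1] == runs[length(runs)]) {
      runs <- runs[-length(runs)]
    }
    expect_equal(anyDuplicated(runs), 0)
  }
})

test_that("the greedy stopping rule matches the exhaustive argmax when unimodal", {
  net <- make_network(c("u1", "u3"), c("u2", "u4"))
  co <- disk_coordinates(c("u1", "u2", "u3", "u4"), rep(1, 4),
                         c(0, 0.1, pi, pi + 0.1))
  a1 <- critical_gap_sweep(net, co)
  a2 <- critical_gap_sweep(net, co, stop_at_first_decrease = TRUE)
  expect_equal(a2$Q, a1$Q)
  expect_equal(a2$n_communities, a1$n_communities)
})

test_that("the uniform-layout critical gap matches its integral and simulation", {
  expect_equal(critical_gap_gpa(2000), 2 * pi * log(2000) / 2000)
  expect_equal(critical_gap_gpa(2000), 0.023877, tolerance = 1e-4)
  for (n in c(100, 1000, 10000)) {
    expect_equal(n * critical_gap_gpa(n) / (2 * pi * log(n)), 1,
                 tolerance = 1e-12)
  }
  # the exact expectation equals 2*pi*H_n/n (largest of n exponential
  # spacings); check the quadrature against the independent harmonic sum
  for (n in c(100, 1000)) {
    expect_equal(critical_gap_gpa(n, "quadrature"),
                 2 * pi * sum(1 / seq_len(n)) / n, tolerance = 1e-6)
  }
  # Monte-Carlo: expected maximum circular gap of n uniform angles
  n <- 1000; reps <- 2000
  mx <- withr::with_seed(5, replicate(reps, {
    th <- sort(runif(n, 0, 2 * pi))
    max(diff(c(th, th[1] + 2 * pi)))
  }))
  se <- sd(mx) / sqrt(reps)
  expect_lt(abs(mean(mx) - critical_gap_gpa(n, "quadrature")), 2 * se)
})

test_that("the Gaussian-mixture critical gap uses the folded-normal mean", {
  expect_equal(critical_gap_npso(1000, 0, 0.1),
               log(1000) * 0.1 * sqrt(2 / pi), tolerance = 1e-12)
  expect_equal(critical_gap_npso(1000, 0, 0.1), 0.5512, tolerance = 1e-3)
  # folded mean against simulation, mu = 0 and mu > 0
  for (mu in c(0, 0.05)) {
    x <- withr::with_seed(9, abs(rnorm(2e5, mu, 0.1)))
    inv_lambda <- critical_gap_npso(exp(1), mu, 0.1)  # log(e) = 1
    se <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - inv_lambda), 2 * se)
  }
  expect_error(critical_gap_npso(1000, 0, 0), "positive")
})
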