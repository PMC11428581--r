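test_that("modularity matches hand-computed single-layer values", {
  # two disconnected unweighted triangles, triangles as communities: Q = 1/2
  A <- matrix(0, 6, 6)
  for (p in list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6)))
    A[p[1], p[2]] <- A[p[2], p[1]] <- 1
  net <- dynamic_network(array(A, c(6, 6, 1)))
  lab <- matrix(rep(1:2, each = 3), 6, 1)
  expect_equal(modularity_value(net, lab), 0.5, tolerance = 1e-12)

  # one community holding everything: Q = 0 for any graph
  expect_equal(modularity_value(net, matrix(1, 6, 1)), 0, tolerance = 1e-12)
  set.seed(2)
  rnet <- dynamic_network(random_tensor(5, 1, seed = 2))
  expect_equal(modularity_value(rnet, matrix(1, 5, 1)), 0, tolerance = 1e-12)
})

test_that("modularity agrees with a single-layer reference implementation", {
  skip_if_not_installed("igraph")
  set.seed(3)
  tensor <- random_tensor(7, 1, seed = 3, density = 0.6)
  net <- dynamic_network(tensor)
  lab <- matrix(sample(1:3, 7, replace = TRUE), 7, 1)
  g <- igraph::graph_from_adjacency_matrix(tensor[, , 1], mode = "undirected",
                                           weighted = TRUE)
  q_ref <- igraph::modularity(g, lab[, 1], weights = igraph::E(g)$weight)
  expect_equal(modularity_value(net, lab), q_ref, tolerance = 1e-10)
})

test_that("persistence versus switching matches the term-by-term hand expansion", {
  # 2-node, 2-layer toy, one unit edge per layer.  Per layer 2m_s = 2, so
  # 2mu = 2 + 2 + 2 omega N (T - 1) = 4 + 4 omega.  Splitting node 1 off in
  # layer 2 loses the coupling term 2 omega and the layer-2 cross pair
  # 2 (A_12 - k_1 k_2 / 2m) = 2 (1 - 1/2) = 1, so
  # Q_persistent - Q_switching = (2 omega + 1) / 2mu.
  A <- matrix(c(0, 1, 1, 0), 2, 2)
  tensor <- array(A, c(2, 2, 2))
  net <- dynamic_network(tensor)
  for (omega in c(0.5, 1, 2)) {
    params <- modularity_params(omega = omega)
    twomu <- 4 + 4 * omega
    persistent <- matrix(1, 2, 2)
    switching <- matrix(c(1, 1, 2, 1), 2, 2)  # node 1 changes in layer 2
    dq <- modularity_value(net, persistent, params) -
      modularity_value(net, switching, params)
    expect_equal(dq, (2 * omega + 1) / twomu, tolerance = 1e-12)
    # the independent brute-force sum agrees on both partitions
    expect_equal(modularity_value(net, switching, params),
                 brute_modularity(tensor, switching, 1, omega),
                 tolerance = 1e-12)
  }
})

test_that("modularity matches the brute-force quadruple sum on random instances", {
  for (seed in 1:8) {
    N <- sample(3:6, 1)
    T <- sample(1:4, 1)
    tensor <- random_tensor(N, T, seed = seed, density = 0.7)
    net <- dynamic_network(tensor)
    gamma <- runif(1, 0.5, 1.5)
    omega <- runif(1, 0, 2)
    lab <- matrix(sample(1:3, N * T, replace = TRUE), N, T)
    expect_equal(modularity_value(net, lab,
                                  modularity_params(gamma = gamma,
                                                    omega = omega)),
                 brute_modularity(tensor, lab, gamma, omega),
                 tolerance = 1e-10)
  }
})

test_that("modularity is invariant to community-id permutation", {
  set.seed(21)
  tensor <- random_tensor(5, 3, seed = 21)
  net <- dynamic_network(tensor)
  lab <- matrix(sample(1:4, 15, replace = TRUE), 5, 3)
  q0 <- modularity_value(net, lab)
  for (rep in 1:10) {
    perm <- sample(1:4)
    expect_equal(modularity_value(net, matrix(perm[lab], 5, 3)), q0,
                 tolerance = 1e-12)
  }
})

test_that("empty layers are rejected as degenerate", {
  tensor <- array(0, c(3, 3, 2))
  tensor[1, 2, 1] <- tensor[2, 1, 1] <- 1  # layer 2 left empty
  net <- dynamic_network(tensor)
  expect_error(modularity_value(net, matrix(1, 3, 2)), "degenerate layer")
})

test_that("optimizer recovers planted blocks and reports self-consistent Q", {
  net <- planted_block_net(n = 8, T = 3, within = 0.9, between = 0)
  p <- louvain_optimize(net, modularity_params(seed = 42))
  block <- rep(1:2, each = 4)
  for (t in 1:3) {
    lab <- p$labels[, t]
    expect_equal(length(unique(lab)), 2)
    expect_true(all(tapply(lab, block, function(v) length(unique(v))) == 1))
  }
  expect_equal(p$q_value,
               modularity_value(net, p$labels, p$params),
               tolerance = 1e-10)
  expect_true(all(p$q_trace > 0))
})

test_that("huge coupling forces labels constant across layers", {
  set.seed(77)
  net <- dynamic_network(random_tensor(6, 4, seed = 77, density = 0.8))
  p <- louvain_optimize(net, modularity_params(omega = 100, seed = 3))
  expect_true(all(p$labels == p$labels[, 1]))
})

test_that("zero coupling decouples layers into independent partitions", {
  # with omega = 0 the quality function is the strength-weighted sum of
  # per-layer single-layer modularities; check Q additivity on the result
  net <- planted_block_net(n = 6, T = 2, within = 0.8, between = 0.05,
                           jitter = 0.1, seed = 12)
  params <- modularity_params(omega = 0, seed = 9)
  p <- louvain_optimize(net, params)
  q_joint <- modularity_value(net, p$labels, params)
  twom <- apply(net$tensor, 3, sum)
  q_layers <- sapply(1:2, function(t) {
    single <- dynamic_network(net$tensor[, , t, drop = FALSE])
    modularity_value(single, p$labels[, t, drop = FALSE], params)
  })
  expect_equal(q_joint, sum(q_layers * twom / sum(twom)), tolerance = 1e-10)
})

test_that("optimizer attains the exhaustive optimum on tiny instances", {
  # 4 nodes x 2 layers (8 node-layer tuples), planted two blocks
  net <- planted_block_net(n = 4, T = 2, within = 0.9, between = 0.1,
                           jitter = 0.05, seed = 8)
  ref <- exhaustive_optimum(net)
  hits <- 0
  for (seed in 1:100) {
    p <- louvain_optimize(net, modularity_params(seed = seed))
    if (abs(p$q_value - ref$q_value) < 1e-9) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("ensembles are deterministic and ordered by run seed", {
  net <- planted_block_net(n = 6, T = 2, within = 0.7, between = 0.1,
                           jitter = 0.2, seed = 31)
  e1 <- run_ensemble(net, modularity_params(seed = 100), n_runs = 5)
  e2 <- run_ensemble(net, modularity_params(seed = 100), n_runs = 5)
  expect_length(e1, 5)
  expect_equal(sapply(e1, `[[`, "q_value"), sapply(e2, `[[`, "q_value"))
  expect_equal(sapply(e1, `[[`, "run_seed"), 101:105)
  for (r in 1:5) expect_identical(e1[[r]]$labels, e2[[r]]$labels)

  expect_length(run_ensemble(net, n_runs = 1), 1)
  expect_error(run_ensemble(net, n_runs = 0), "positive")
})

test_that("negative correlations are clipped under the default policy", {
  tensor <- array(0, c(3, 3, 1))
  tensor[1, 2, 1] <- tensor[2, 1, 1] <- 0.8
  tensor[1, 3, 1] <- tensor[3, 1, 1] <- -0.5
  tensor[2, 3, 1] <- tensor[3, 2, 1] <- 0.2
  net <- dynamic_network(tensor)
  lab <- matrix(c(1, 1, 2), 3, 1)
  clipped <- pmax(tensor, 0)
  expect_equal(modularity_value(net, lab),
               brute_modularity(clipped, lab, 1, 1), tolerance = 1e-12)
  # "keep" policy uses the raw weights
  expect_equal(modularity_value(net, lab,
                                modularity_params(negative_policy = "keep")),
               brute_modularity(tensor, lab, 1, 1), tolerance = 1e-12)
})
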