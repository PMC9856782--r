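test_that("modularity closed forms hold on constructed graphs", {
  net <- toy_network(two_triangles())
  # one module spanning everything always telescopes to 0
  expect_equal(modularity_q(net, rep(1, 6)), 0, tolerance = 1e-12)
  # the true two-triangle split: each module contributes 3/6 - (6/12)^2
  expect_equal(modularity_q(net, c(1, 1, 1, 2, 2, 2)), 0.5, tolerance = 1e-12)
  # moving one node across strictly hurts
  expect_lt(modularity_q(net, c(1, 1, 2, 2, 2, 2)), 0.5)
  expect_error(modularity_q(net, c(1, 1, 1)), "cover")
  empty <- toy_network(matrix(0, 3, 3) + diag(0, 3))
  expect_error(modularity_q(empty, rep(1, 3)), "no edges")
})

test_that("weighted modularity agrees with igraph on 0/1 graphs", {
  set.seed(17)
  for (i in 1:10) {
    w <- random_graph_matrix(8, 0.4)
    if (sum(w) == 0) next
    net <- toy_network(w)
    assignment <- sample(1:3, 8, replace = TRUE)
    g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected")
    expect_equal(modularity_q(net, assignment),
                 igraph::modularity(g, assignment), tolerance = 1e-12)
  }
})

test_that("brute force enumeration finds the exact optimum", {
  # 2 nodes, 1 edge: any split scores negative, single module scores 0
  pair <- toy_network(edges_to_matrix(2, list(c(1, 2, 1))))
  bf <- brute_force_modules(pair)
  expect_equal(bf$n_modules, 1L)
  expect_equal(bf$q, 0, tolerance = 1e-12)

  bf_tri <- brute_force_modules(toy_network(two_triangles()))
  expect_equal(bf_tri$q, 0.5, tolerance = 1e-12)
  expect_equal(bf_tri$assignment[1:3], rep(bf_tri$assignment[1], 3))
  expect_equal(bf_tri$n_modules, 2L)

  big <- toy_network(random_graph_matrix(12, 0.5))
  expect_error(brute_force_modules(big), "limited")
})

test_that("detected modules recover planted structure and bound brute force", {
  net <- toy_network(two_triangles())
  part <- detect_modules(net, seed = 4)
  expect_equal(part$q, 0.5, tolerance = 1e-12)
  expect_equal(part$n_modules, 2L)

  # three disconnected 4-cliques: exact recovery expected
  w <- matrix(0, 12, 12)
  for (b in 0:2) w[b * 4 + 1:4, b * 4 + 1:4] <- 1
  diag(w) <- 0
  cliq <- toy_network(w)
  part_c <- detect_modules(cliq, seed = 1)
  expect_equal(part_c$n_modules, 3L)
  expect_equal(part_c$q, modularity_q(cliq, rep(1:3, each = 4)),
               tolerance = 1e-12)

  set.seed(23)
  for (i in 1:8) {
    w <- random_graph_matrix(7, 0.45)
    if (sum(w) == 0) next
    net_i <- toy_network(w)
    expect_gte(detect_modules(net_i, seed = i)$q,
               brute_force_modules(net_i)$q - 0.05)
    expect_gte(detect_modules(net_i, seed = i)$q, -1e-12)
  }

  # uniform clique: no structure to find, Q stays at the baseline
  clique <- toy_network(matrix(1, 6, 6) - diag(6))
  expect_lte(detect_modules(clique, seed = 2)$q, 1e-12)
})

test_that("detection is deterministic given a seed and permutation-equivariant", {
  spec <- block_spec(80, k = 4, seed = 31)
  net <- build_network(simulate_cohort(spec))
  p1 <- detect_modules(net, seed = 9)
  p2 <- detect_modules(net, seed = 9)
  expect_identical(p1$assignment, p2$assignment)

  # relabeling nodes permutes the partition identically
  perm <- sample(68)
  w_perm <- net$weights[perm, perm]
  net_perm <- toy_network(w_perm)
  net_perm$threshold_fraction <- net$threshold_fraction
  p_perm <- detect_modules(net_perm, seed = 9)
  agree <- outer(p1$assignment[perm], p1$assignment[perm], "==") ==
    outer(p_perm$assignment, p_perm$assignment, "==")
  expect_true(all(agree))
})

test_that("partitions are canonicalized largest-module-first", {
  part <- module_partition(c(3, 3, 1, 1, 1, 2))
  expect_equal(part$assignment, c(2, 2, 1, 1, 1, 3))
  expect_equal(part$module_sizes, c(3L, 2L, 1L))
  listing <- partition_table(module_partition(rep(1:2, 34)))
  expect_equal(nrow(listing), 68L)
  expect_true(!is.unsorted(listing$module_id))
})
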