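test_that("within-module degree z-score matches hand evaluation", {
  sp <- star_plus_pair()
  net <- toy_network(sp$w)
  z <- within_module_degree_z(net, sp$partition)
  # star module degrees (4,1,1,1,1): mean 1.6, population SD 1.2
  expect_equal(unname(z[1]), 2.0, tolerance = 1e-12)
  expect_equal(unname(z[2:5]), rep(-0.5, 4), tolerance = 1e-12)
  # two-node module has equal degrees: sigma = 0 convention
  expect_equal(unname(z[6:7]), c(0, 0))

  # singleton module and equal-degree module both give Z = 0
  tri <- toy_network(two_triangles())
  expect_equal(unname(within_module_degree_z(tri, c(1, 1, 1, 2, 2, 2))),
               rep(0, 6))
})

test_that("z-scores standardize exactly within every informative module", {
  set.seed(41)
  for (i in 1:10) {
    w <- random_graph_matrix(12, 0.4)
    if (sum(w) == 0) next
    net <- toy_network(w)
    assignment <- sample(1:3, 12, replace = TRUE)
    z <- within_module_degree_z(net, assignment)
    for (m in unique(assignment)) {
      nodes <- which(assignment == m)
      K <- rowSums(net$adjacency[nodes, nodes, drop = FALSE])
      if (sqrt(mean((K - mean(K))^2)) > 0) {
        expect_lt(abs(mean(z[nodes])), 1e-12)
        expect_lt(abs(sqrt(mean((z[nodes] - mean(z[nodes]))^2)) - 1), 1e-12)
      }
    }
  }
})

test_that("participation coefficient matches its closed forms", {
  # all links within the node's own module
  tri <- toy_network(two_triangles())
  expect_equal(unname(participation_coefficient(tri, c(1, 1, 1, 2, 2, 2))),
               rep(0, 6))
  # 2 links split over 2 modules: 1 - (1/4 + 1/4) = 0.5
  w <- edges_to_matrix(3, list(c(1, 2, 1), c(1, 3, 1)))
  p <- participation_coefficient(toy_network(w), c(1, 1, 2))
  expect_equal(unname(p[1]), 0.5)
  # 4 links uniform over 4 modules: 1 - 4/16 = 0.75
  w4 <- edges_to_matrix(5, list(c(1, 2, 1), c(1, 3, 1), c(1, 4, 1), c(1, 5, 1)))
  p4 <- participation_coefficient(toy_network(w4), c(1, 1, 2, 3, 4))
  expect_equal(unname(p4[1]), 0.75)
  # isolated node: P = 0 by convention
  iso <- edges_to_matrix(3, list(c(1, 2, 1)))
  expect_equal(unname(participation_coefficient(toy_network(iso),
                                                c(1, 1, 2))[3]), 0)
})

test_that("degree decompositions and P bounds hold on random graphs", {
  set.seed(43)
  for (i in 1:10) {
    w <- random_graph_matrix(15, 0.35)
    if (sum(w) == 0) next
    net <- toy_network(w)
    k_modules <- sample(2:4, 1)
    assignment <- sample(seq_len(k_modules), 15, replace = TRUE)
    adj <- net$adjacency
    Ki <- rowSums(adj)
    Kci <- vapply(sort(unique(assignment)), function(m)
      rowSums(adj[, assignment == m, drop = FALSE]), numeric(15))
    expect_equal(rowSums(Kci), Ki, ignore_attr = TRUE)
    p <- participation_coefficient(net, assignment)
    expect_true(all(p >= 0))
    expect_true(all(p <= 1 - 1 / length(unique(assignment)) + 1e-12))
  }
})

test_that("lobe connectivity computes both intra readings plus mean P", {
  rt <- dk_region_table()
  spec <- simulation_spec(n_subjects = 40, seed = 3)
  net <- build_network(simulate_cohort(spec))
  rep_w <- lobe_connectivity(net, mode = "weight")
  rep_l <- lobe_connectivity(net, mode = "literal")
  expect_equal(rep_w$lobe, c("frontal", "temporal", "parietal", "occipital"))
  expect_equal(rep_w$intra, rep_w$intra_weight)
  expect_equal(rep_l$intra, rep_l$intra_literal)
  # z-scores average to zero per defining module whenever sigma > 0
  expect_true(all(abs(rep_l$intra_literal) < 1e-10))
  expect_error(lobe_connectivity(net, mode = "bogus"))

  # hand-checkable toy: 8 nodes, 2 lobes, known weights
  w <- edges_to_matrix(8, list(c(1, 2, 0.6), c(2, 3, 0.4), c(5, 6, 0.8),
                               c(7, 8, 0.2), c(1, 8, 0.5)))
  toy_rt <- data.frame(id = 1:8, lobe = rep(c("front", "back"), each = 4))
  toy_net <- toy_network(w)
  toy_rep <- lobe_connectivity(toy_net, region_table = toy_rt, mode = "weight")
  # within-lobe retained weights: front (0.6, 0.4), back (0.8, 0.2)
  expect_equal(toy_rep$intra_weight, c(0.5, 0.5))
  expect_equal(toy_rep$n_within_edges, c(2L, 2L))
  assignment <- as.integer(factor(toy_rt$lobe, levels = c("front", "back")))
  P <- participation_coefficient(toy_net, assignment)
  expect_equal(toy_rep$inter, c(mean(P[1:4]), mean(P[5:8])))
})

test_that("link counts split within-lobe edges by hemisphere", {
  rt <- dk_region_table()
  # three known frontal edges: L-L (1,3), R-R (2,4), bilateral (1,2)
  w <- matrix(0, 68, 68)
  w[1, 3] <- w[3, 1] <- 0.9
  w[2, 4] <- w[4, 2] <- 0.8
  w[1, 2] <- w[2, 1] <- 0.7
  w[29, 47] <- w[47, 29] <- 0.6 # cross-lobe edge, counted nowhere
  net <- toy_network(w, region_table = rt)
  lc <- link_counts(net)
  expect_equal(lc$L[lc$lobe == "frontal"], 1L)
  expect_equal(lc$R[lc$lobe == "frontal"], 1L)
  expect_equal(lc$B[lc$lobe == "frontal"], 1L)
  expect_equal(sum(lc$L + lc$R + lc$B), 3L)
  # oracle: brute scan restricted to each lobe
  for (lb in unique(rt$lobe)) {
    nodes <- rt$id[rt$lobe == lb]
    total <- sum(net$adjacency[nodes, nodes]) / 2
    row <- lc[lc$lobe == lb, ]
    expect_equal(row$L + row$R + row$B, total)
  }
  empty <- toy_network(matrix(0, 68, 68), region_table = rt)
  expect_true(all(link_counts(empty)[, c("L", "R", "B")] == 0))
})

test_that("connectivity ratios are percentages of the reference group", {
  a <- data.frame(lobe = c("frontal", "temporal"), intra = c(0.4, 0.5),
                  inter = c(0.6, 0.6))
  expect_equal(unname(connectivity_ratio(a, a)), c(100, 100))
  b <- a; b$intra <- c(0.2, 0.5)
  expect_equal(unname(connectivity_ratio(a, b)), c(50, 100))
  z <- a; z$intra[1] <- 0
  expect_error(connectivity_ratio(z, a), "denominator")
  swapped <- a[2:1, ]
  expect_error(connectivity_ratio(a, swapped), "same lobes")
})

test_that("planted group contrast lowers connectivity ratios in simulation", {
  spec_a <- block_spec(60, k = 4, rho_within = 0.55, rho_between = 0.1, seed = 51)
  spec_b <- block_spec(60, k = 4, rho_within = 0.25, rho_between = 0.1, seed = 52)
  net_a <- build_network(simulate_cohort(spec_a, "A"))
  net_b <- build_network(simulate_cohort(spec_b, "B"))
  ratios <- connectivity_ratio(lobe_connectivity(net_a),
                               lobe_connectivity(net_b))
  expect_true(all(ratios < 100))
})
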