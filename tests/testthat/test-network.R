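test_that("correlation matrix matches the Pearson formula and its limits", {
  rt <- dk_region_table()
  set.seed(3)
  vals <- matrix(rnorm(10 * 68, mean = 2.2, sd = 0.05), 10, 68)
  vals[, 2] <- 2 * vals[, 1]          # perfect positive linear relation
  vals[, 3] <- -vals[, 1] + 5         # perfect negative
  cohort <- fd_cohort(vals, region_table = rt)
  cm <- correlation_matrix(cohort)
  expect_equal(cm[1, 2], 1)
  expect_equal(cm[1, 3], -1)
  expect_equal(diag(cm), rep(1, 68), ignore_attr = TRUE)

  # hand-evaluated Pearson on a 4-subject toy pair
  a <- c(1, 2, 3, 4); b <- c(2, 1, 4, 3)
  num <- sum((a - mean(a)) * (b - mean(b)))
  den <- sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  vals[1:4, 5] <- a; vals[1:4, 6] <- b
  cm2 <- correlation_matrix(fd_cohort(vals[1:4, ], region_table = rt))
  expect_equal(cm2[5, 6], num / den)

  vals[, 7] <- 2.2 # zero variance is an error naming the region
  expect_error(correlation_matrix(fd_cohort(vals, region_table = rt)),
               "MOrF_L") # region id 7 = left medial orbital frontal
  expect_error(correlation_matrix(fd_cohort(vals[1:2, ], region_table = rt)),
               "3 subjects")
})

test_that("proportional threshold retains exactly the strongest-pair quota", {
  set.seed(10)
  m <- matrix(runif(68 * 68, 0.01, 1), 68, 68)
  m <- (m + t(m)) / 2; diag(m) <- 1
  net <- proportional_threshold(m, fraction = 0.2)
  expect_equal(net$n_edges, floor(0.2 * choose(68, 2)))
  expect_equal(net$n_edges, 455L)
  expect_equal(sum(net$adjacency) / 2, 455)
  expect_equal(diag(net$weights), rep(0, 68), ignore_attr = TRUE)
  expect_true(isSymmetric(net$weights))
  expect_true(all(net$weights[net$adjacency == 1] > 0))
  expect_true(all(net$weights[net$adjacency == 0] == 0))
  # every retained weight dominates every dropped positive weight
  dropped <- m[upper.tri(m)][net$weights[upper.tri(net$weights)] == 0]
  expect_true(min(net$weights[net$weights > 0]) >= max(dropped[dropped > 0]))

  neg <- -abs(m); diag(neg) <- 1
  expect_equal(proportional_threshold(neg, 0.2)$n_edges, 0L)
  expect_equal(proportional_threshold(m, 1)$n_edges, 2278L)
  expect_error(proportional_threshold(m, 0), "fraction")
  expect_error(proportional_threshold(m[1:3, 1:4], 0.2), "square")
  asym <- m; asym[1, 2] <- asym[1, 2] + 0.5
  expect_error(proportional_threshold(asym, 0.2), "symmetric")
})

test_that("thresholding is idempotent and rank-invariant", {
  set.seed(11)
  m <- matrix(rnorm(68 * 68), 68, 68); m <- (m + t(m)) / 2; diag(m) <- 1
  net <- proportional_threshold(m, 0.2)
  again <- proportional_threshold(net$weights, 0.2)
  expect_equal(again$weights, net$weights)
  expect_equal(again$n_edges, net$n_edges)
  # strictly monotone transform of the positive weights keeps the edge set
  warped <- sign(m) * abs(m)^3
  expect_equal(proportional_threshold(warped, 0.2)$adjacency, net$adjacency)
})

test_that("lowered inter-subject correlation shows up as weaker retained edges", {
  spec_a <- block_spec(60, k = 5, rho_within = 0.6, rho_between = 0.1, seed = 21)
  spec_b <- block_spec(60, k = 5, rho_within = 0.3, rho_between = 0.1, seed = 22)
  net_a <- build_network(simulate_cohort(spec_a, "A"))
  net_b <- build_network(simulate_cohort(spec_b, "B"))
  expect_gt(mean(net_a$weights[net_a$weights > 0]),
            mean(net_b$weights[net_b$weights > 0]))
})

test_that("per-lobe mean correlation averages the right block", {
  rt <- dk_region_table()
  cm <- matrix(0.1, 68, 68); diag(cm) <- 1
  occ <- rt$id[rt$lobe == "occipital"]
  cm[occ, occ] <- 0.7; diag(cm) <- 1
  rates <- lobe_mean_correlation(cm, rt)
  expect_equal(unname(rates["occipital"]), 0.7)
  expect_equal(unname(rates["frontal"]), 0.1)
})
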