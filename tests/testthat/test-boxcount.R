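test_that("count_boxes matches direct tiling arithmetic on solids", {
  cube10 <- make_solid_cube(10)
  expect_equal(count_boxes(cube10, 10), 1L)
  expect_equal(count_boxes(cube10, 5), 8L)
  expect_equal(count_boxes(cube10, 2), 125L)
  # partial far-face boxes count: ceil(10/r)^3
  for (r in 1:10)
    expect_equal(count_boxes(cube10, r), as.integer(ceiling(10 / r)^3))
  expect_equal(count_boxes(make_menger_sponge(3), 27), 1L)
  expect_error(count_boxes(cube10, 0), "positive integer")
})

test_that("count_boxes agrees with a naive recount on random volumes", {
  set.seed(2024)
  for (i in 1:25) {
    d <- sample(3:14, 3, replace = TRUE)
    grid <- array(runif(prod(d)) < 0.3, dim = d)
    if (!any(grid)) grid[1, 1, 1] <- TRUE
    for (r in c(1:4, 7, 10))
      expect_equal(count_boxes(grid, r), naive_count_boxes(grid, r),
                   info = sprintf("vol %d r %d", i, r))
  }
})

test_that("box-count series follows the 10-to-2 schedule and is monotone", {
  s <- boxcount_series(make_solid_cube(10))
  expect_equal(s$r, 10:2)
  expect_equal(nrow(s), 9L)
  expect_equal(s$N[s$r == 10], 1L)
  expect_equal(s$N[s$r == 5], 8L)
  expect_equal(s$N[s$r == 2], 125L)
  # single voxel: one box always suffices
  one <- array(FALSE, dim = c(12, 12, 12)); one[5, 5, 5] <- TRUE
  expect_true(all(boxcount_series(one)$N == 1L))
  # N(r) non-increasing in r on random volumes
  set.seed(9)
  for (i in 1:10) {
    g <- array(runif(16^3) < 0.2, dim = c(16, 16, 16))
    if (!any(g)) g[1, 1, 1] <- TRUE
    expect_true(all(diff(boxcount_series(g)$N) >= 0)) # r decreases along rows
  }
  expect_error(boxcount_series(array(FALSE, dim = c(3, 3, 3))), "empty")
})

test_that("fit_fd recovers an exact power law and maximizes R^2", {
  rs <- 10:2
  series <- data.frame(r = rs, N = 2^(2.5 * log2(1 / rs) + 12))
  fit <- fit_fd(series)
  expect_equal(fit$fd, 2.5, tolerance = 1e-10)
  expect_equal(fit$intercept, 12, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # perfect line: tie on R^2 resolved toward the longest window
  expect_equal(unname(fit$window), c(1L, 9L))
  expect_error(fit_fd(series[1:3, ]), "min_window")
  expect_error(fit_fd(data.frame(r = 10:2, N = rep(1, 9))), "constant|equal")
})

test_that("window selection agrees with an exhaustive search oracle", {
  set.seed(31)
  for (i in 1:20) {
    # a bent series: one power law for large boxes, another for small
    rs <- 10:2
    brk <- sample(4:6, 1)
    y <- c(2.8 * log2(1 / rs)[1:brk], NA)[1:9]
    y[(brk + 1):9] <- y[brk] +
      1.6 * (log2(1 / rs)[(brk + 1):9] - log2(1 / rs)[brk])
    y <- y + rnorm(9, sd = 0.01)
    series <- data.frame(r = rs, N = pmax(1, 2^(y - min(y))))
    fit <- fit_fd(series)
    oracle <- naive_best_window(series)
    expect_equal(fit$r_squared, oracle$r2, tolerance = 1e-9)
    expect_equal(fit$fd, oracle$slope, tolerance = 1e-9)
  }
})

test_that("phantoms recover their known dimensions", {
  expect_lt(abs(fit_fd(boxcount_series(make_solid_cube(64)))$fd - 3.0), 0.05)
  expect_lt(abs(fit_fd(boxcount_series(make_slab(64, 1)))$fd - 2.0), 0.1)
  expect_lt(abs(fit_fd(boxcount_series(make_menger_sponge(4)))$fd -
                  log(20) / log(3)), 0.15)
  # any non-empty volume stays in the physically meaningful band
  set.seed(5)
  for (i in 1:10) {
    g <- array(runif(18^3) < runif(1, 0.05, 0.9), dim = c(18, 18, 18))
    if (!any(g)) g[1, 1, 1] <- TRUE
    fd <- fit_fd(boxcount_series(g))$fd
    expect_gt(fd, -0.1); expect_lt(fd, 3.2)
  }
})

test_that("region_fd crops to the region and matches phantom oracles", {
  rt <- dk_region_table()
  labels <- array(0L, dim = c(40, 40, 40))
  labels[3:22, 5:24, 7:26] <- 1L            # solid 20^3 block
  labels[30:39, 30:39, 12] <- 2L            # one-voxel-thick sheet
  parc <- parcellation(labels, region_table = rt)
  expect_lt(abs(region_fd(parc, 1)$fd - 3.0), 0.1)
  expect_lt(abs(region_fd(parc, 2)$fd - 2.0), 0.25)
  expect_error(region_fd(parc, 3), "empty or unknown")
  # cropping makes the fit object-relative: a shifted copy scores the same
  labels2 <- array(0L, dim = c(40, 40, 40))
  labels2[15:34, 11:30, 14:33] <- 1L
  parc2 <- parcellation(labels2, region_table = rt)
  expect_equal(region_fd(parc, 1)$fd, region_fd(parc2, 1)$fd)
})
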