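# Shared fixtures and independent oracles. Everything here is deliberately
# naive/bruteforce so it stays independent of the implementation it checks.

# cov_network from an explicit nonnegative weight matrix: fraction 1 keeps
# every positive pair, so the toy weights pass through unchanged
toy_network <- function(w, region_table = NULL) {
  proportional_threshold(w, fraction = 1, region_table = region_table)
}

# symmetric weight matrix from an edge list (i, j, w)
edges_to_matrix <- function(n, edges) {
  w <- matrix(0, n, n)
  for (e in edges) {
    w[e[1], e[2]] <- e[3]
    w[e[2], e[1]] <- e[3]
  }
  w
}

# two disconnected unit-weight triangles on nodes 1:3 and 4:6
two_triangles <- function() {
  edges_to_matrix(6, list(c(1, 2, 1), c(1, 3, 1), c(2, 3, 1),
                          c(4, 5, 1), c(4, 6, 1), c(5, 6, 1)))
}

# 5-node star (center = node 1) plus a detached 2-node module
star_plus_pair <- function() {
  w <- edges_to_matrix(7, list(c(1, 2, 1), c(1, 3, 1), c(1, 4, 1),
                               c(1, 5, 1), c(6, 7, 1)))
  list(w = w, partition = c(1, 1, 1, 1, 1, 2, 2))
}

# naive triple-loop box recount: anchors tile from the origin, partial
# boxes at the far faces included
naive_count_boxes <- function(grid, r) {
  d <- dim(grid)
  count <- 0L
  for (x0 in seq(1L, d[1], by = r)) {
    for (y0 in seq(1L, d[2], by = r)) {
      for (z0 in seq(1L, d[3], by = r)) {
        if (any(grid[x0:min(x0 + r - 1L, d[1]),
                     y0:min(y0 + r - 1L, d[2]),
                     z0:min(z0 + r - 1L, d[3])]))
          count <- count + 1L
      }
    }
  }
  count
}

# independent exhaustive window search for the log-log fit: R^2 via cor()
# and slope via lm(), scanning all contiguous windows of length >= min_window
naive_best_window <- function(series, min_window = 4L) {
  x <- log2(1 / series$r)
  y <- log2(series$N)
  n <- length(x)
  best <- list(r2 = -1, start = NA, end = NA)
  for (s in seq_len(n - min_window + 1L)) {
    for (e in seq.int(s + min_window - 1L, n)) {
      ys <- y[s:e]
      r2 <- if (stats::sd(ys) == 0) 0 else stats::cor(x[s:e], ys)^2
      if (r2 > best$r2 + 1e-12) best <- list(r2 = r2, start = s, end = e)
    }
  }
  best$slope <- unname(stats::coef(stats::lm(y[best$start:best$end] ~
                                               x[best$start:best$end]))[2])
  best
}

# hand-written Benjamini-Hochberg step-up: q_(i) = min_{j>=i} p_(j) m / j
naive_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[ord] * m / seq_len(m)))))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# random binary symmetric weight matrix for property sweeps
random_graph_matrix <- function(n, p_edge = 0.5) {
  w <- matrix(0, n, n)
  ut <- which(upper.tri(w))
  on <- ut[stats::runif(length(ut)) < p_edge]
  w[on] <- 1
  w + t(w)
}

# small simulation spec on the full atlas with k equal-ish planted blocks
block_spec <- function(n_subjects, k = 5, rho_within = 0.6, rho_between = 0.1,
                       seed = 11, ...) {
  rt <- dk_region_table()
  blocks <- sort(rep_len(seq_len(k), nrow(rt)))
  simulation_spec(n_subjects = n_subjects, planted_modules = blocks,
                  rho_within = rho_within, rho_between = rho_between,
                  effect_regions = integer(), effect_d = 0,
                  seed = seed, region_table = rt, ...)
}
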