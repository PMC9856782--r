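#' Within-module degree z-score
#'
#' For each node, counts its binary links to other nodes of its own module
#' (K_i) and standardizes against that module's degree distribution:
#' Z_i = (K_i - mean(K)) / sd(K), with the population (no n-1 correction)
#' standard deviation. Modules with sd 0 (including singletons) get Z = 0
#' by convention.
#'
#' @param network a `cov_network`.
#' @param partition a `module_partition` (or assignment vector) covering
#'   the network.
#' @return Numeric vector of Z_i, one per node.
#' @export
within_module_degree_z <- function(network, partition) {
  adj <- binary_adjacency(network)
  assignment <- partition_assignment(partition, nrow(adj))
  z <- numeric(nrow(adj))
  for (m in unique(assignment)) {
    nodes <- which(assignment == m)
    K <- rowSums(adj[nodes, nodes, drop = FALSE])
    sigma <- sqrt(mean((K - mean(K))^2))
    z[nodes] <- if (sigma > 0) (K - mean(K)) / sigma else 0
  }
  names(z) <- rownames(network$weights)
  z
}

#' Participation coefficient
#'
#' P_i = 1 - sum_c (K_ci / K_i)^2, where K_ci is the number of binary
#' links of node i into module c and K_i its total degree. P is 0 when all
#' links stay inside the node's own module and approaches 1 when links are
#' spread uniformly over all modules. Isolated nodes (K_i = 0) get P = 0
#' by convention.
#'
#' @inheritParams within_module_degree_z
#' @return Numeric vector of P_i in `[0, 1]`, one per node.
#' @export
participation_coefficient <- function(network, partition) {
  adj <- binary_adjacency(network)
  assignment <- partition_assignment(partition, nrow(adj))
  mods <- sort(unique(assignment))
  # K_ci: links of node i terminating in module c
  Kci <- vapply(mods, function(m)
    rowSums(adj[, assignment == m, drop = FALSE]), numeric(nrow(adj)))
  Ki <- rowSums(adj)
  p <- ifelse(Ki > 0, 1 - rowSums((Kci / pmax(Ki, 1))^2), 0)
  names(p) <- rownames(network$weights)
  p
}

#' Lobe-level intra- and inter-lobular connectivity
#'
#' Treats the four anatomical lobes (hemispheres pooled) as the module
#' partition. Inter-lobular connectivity of a lobe is the mean
#' participation coefficient of its nodes. Intra-lobular connectivity is
#' reported in two modes: `"weight"` (headline) — the mean retained edge
#' weight among edges with both endpoints in the lobe; `"literal"` — the
#' mean within-module degree z-score of the lobe's nodes, which is 0 by
#' construction whenever the lobe's degree spread is nonzero. Both
#' candidate readings are always computed and returned.
#'
#' @param network a `cov_network`.
#' @param region_table a region table aligned with the network nodes.
#' @param mode which intra-lobular reading the `intra` column carries.
#' @return A data.frame of class `lobe_connectivity` with one row per lobe
#'   and columns `lobe`, `intra`, `inter`, `intra_weight`, `intra_literal`,
#'   `n_within_edges`.
#' @export
lobe_connectivity <- function(network, region_table = network$region_table,
                              mode = c("weight", "literal")) {
  mode <- match.arg(mode)
  if (is.null(region_table)) stop("a region table is required")
  n <- nrow(network$weights)
  if (nrow(region_table) != n)
    stop("region table does not match the network size")
  lobes <- unique(region_table$lobe)
  assignment <- as.integer(factor(region_table$lobe, levels = lobes))
  P <- participation_coefficient(network, assignment)
  Z <- within_module_degree_z(network, assignment)
  w <- network$weights
  rows <- lapply(seq_along(lobes), function(m) {
    nodes <- which(assignment == m)
    sub <- w[nodes, nodes, drop = FALSE]
    ww <- sub[upper.tri(sub)]
    ww <- ww[ww != 0]
    data.frame(lobe = lobes[m],
               inter = mean(P[nodes]),
               intra_weight = if (length(ww)) mean(ww) else 0,
               intra_literal = mean(Z[nodes]),
               n_within_edges = length(ww))
  })
  out <- do.call(rbind, rows)
  out$intra <- if (mode == "weight") out$intra_weight else out$intra_literal
  out <- out[, c("lobe", "intra", "inter", "intra_weight", "intra_literal",
                 "n_within_edges")]
  class(out) <- c("lobe_connectivity", "data.frame")
  out
}

#' Within-lobe link counts by hemisphere
#'
#' For each lobe, counts the retained edges with both endpoints in that
#' lobe, split into L (both endpoints left), R (both right) and B (one in
#' each hemisphere).
#'
#' @inheritParams lobe_connectivity
#' @return data.frame with columns `lobe`, `L`, `R`, `B`.
#' @export
link_counts <- function(network, region_table = network$region_table) {
  if (is.null(region_table)) stop("a region table is required")
  adj <- binary_adjacency(network)
  lobes <- unique(region_table$lobe)
  rows <- lapply(lobes, function(lb) {
    nodes <- which(region_table$lobe == lb)
    hemi <- region_table$hemisphere[nodes]
    sub <- adj[nodes, nodes, drop = FALSE]
    ij <- which(upper.tri(sub) & sub == 1L, arr.ind = TRUE)
    h1 <- hemi[ij[, 1]]; h2 <- hemi[ij[, 2]]
    data.frame(lobe = lb,
               L = sum(h1 == "L" & h2 == "L"),
               R = sum(h1 == "R" & h2 == "R"),
               B = sum(h1 != h2))
  })
  do.call(rbind, rows)
}

#' Connectivity ratio between two lobe reports
#'
#' Per-lobe percentage 100 * (group B metric / group A metric), the
#' "ratio vs reference" used to compare a patient group against controls.
#'
#' @param report_a,report_b `lobe_connectivity` data.frames with the same
#'   lobes in the same order.
#' @param metric which column to ratio (default the headline `intra`).
#' @param zero how to treat a zero reference value: `"error"` (default) or
#'   `"na"` to return NA for that lobe.
#' @return Named numeric vector of percentages, one per lobe.
#' @export
connectivity_ratio <- function(report_a, report_b, metric = "intra",
                               zero = c("error", "na")) {
  zero <- match.arg(zero)
  if (!identical(report_a$lobe, report_b$lobe))
    stop("reports must cover the same lobes in the same order")
  a <- report_a[[metric]]; b <- report_b[[metric]]
  if (any(a == 0) && zero == "error")
    stop("zero denominator in lobe ",
         paste(report_a$lobe[a == 0], collapse = ", "))
  out <- ifelse(a == 0, NA_real_, 100 * b / a)
  names(out) <- report_a$lobe
  out
}

#' Node-level metric table
#'
#' Binary degree, within-module degree z-score and participation
#' coefficient for every node under a given partition.
#'
#' @inheritParams within_module_degree_z
#' @return data.frame with columns `node`, `module_id`, `K`, `Z`, `P`.
#' @export
node_metrics <- function(network, partition) {
  adj <- binary_adjacency(network)
  assignment <- partition_assignment(partition, nrow(adj))
  labs <- rownames(network$weights)
  if (is.null(labs)) labs <- as.character(seq_len(nrow(adj)))
  data.frame(node = labs,
             module_id = assignment,
             K = rowSums(adj),
             Z = unname(within_module_degree_z(network, assignment)),
             P = unname(participation_coefficient(network, assignment)))
}

binary_adjacency <- function(network) {
  if (inherits(network, "cov_network")) network$adjacency
  else (as.matrix(network) != 0) * 1L
}

partition_assignment <- function(partition, n) {
  assignment <- if (inherits(partition, "module_partition"))
    partition$assignment else as.integer(partition)
  if (length(assignment) != n || anyNA(assignment))
    stop("partition must cover all ", n, " nodes")
  assignment
}
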