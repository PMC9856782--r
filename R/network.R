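#' Inter-regional correlation matrix of a cohort
#'
#' Pearson (default) product-moment correlation of FD values between every
#' pair of regions, across subjects. This is the raw structural covariance
#' map from which the group network is thresholded.
#'
#' @param cohort an `fd_cohort`.
#' @param method `"pearson"` (the structural-covariance default) or
#'   `"spearman"`.
#' @return A symmetric 68x68 correlation matrix with unit diagonal,
#'   dimnames = region labels.
#' @export
correlation_matrix <- function(cohort, method = c("pearson", "spearman")) {
  stopifnot(inherits(cohort, "fd_cohort"))
  method <- match.arg(method)
  vals <- cohort$values
  if (nrow(vals) < 3L)
    stop("need at least 3 subjects to correlate regions")
  sds <- apply(vals, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance region(s): ",
         paste(colnames(vals)[sds == 0], collapse = ", "))
  stats::cor(vals, method = method)
}

#' Proportional thresholding of a covariance matrix
#'
#' Ranks the unique off-diagonal correlations in descending order and
#' retains the strongest `fraction` of the n(n-1)/2 region pairs
#' (floor(fraction * 2278) = 455 edges at the default 0.2 on 68 nodes),
#' keeping only strictly positive coefficients; everything else, negative
#' correlations, and the diagonal are set to 0. Ties at the cutoff are
#' broken by value descending, then by (row, column) order, so the edge
#' set is deterministic.
#'
#' @param mat square symmetric numeric matrix (e.g. from
#'   [correlation_matrix()]).
#' @param fraction proportion of pairs to retain, in (0, 1].
#' @param region_table optional region table carried on the result.
#' @return An object of class `cov_network` with elements `weights`
#'   (retained coefficients, 0 elsewhere), `adjacency` (binary mask),
#'   `threshold_fraction`, `n_edges` and `region_table`.
#' @export
proportional_threshold <- function(mat, fraction = 0.2, region_table = NULL) {
  if (!is.matrix(mat) || nrow(mat) != ncol(mat))
    stop("input must be a square matrix")
  if (!isSymmetric(unname(mat), tol = 1e-10))
    stop("input matrix must be symmetric")
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]")
  n <- nrow(mat)
  ut <- which(upper.tri(mat), arr.ind = TRUE)
  vals <- mat[ut]
  quota <- floor(fraction * nrow(ut))
  ord <- order(-vals, ut[, 1], ut[, 2])
  take <- ord[seq_len(quota)]
  take <- take[vals[take] > 0] # negatives and zeros never become links

  weights <- matrix(0, n, n, dimnames = dimnames(mat))
  if (length(take)) {
    ij <- ut[take, , drop = FALSE]
    weights[ij] <- vals[take]
    weights[ij[, c(2, 1), drop = FALSE]] <- vals[take]
  }
  adjacency <- (weights != 0) * 1L
  structure(list(weights = weights, adjacency = adjacency,
                 threshold_fraction = fraction,
                 n_edges = length(take),
                 region_table = region_table),
            class = "cov_network")
}

#' @export
print.cov_network <- function(x, ...) {
  cat(sprintf("<cov_network> %d nodes, %d retained edges (fraction %.3g)\n",
              nrow(x$weights), x$n_edges, x$threshold_fraction))
  invisible(x)
}

#' Build the group covariance network from a cohort
#'
#' Convenience composition of [correlation_matrix()] and
#' [proportional_threshold()].
#'
#' @inheritParams correlation_matrix
#' @inheritParams proportional_threshold
#' @return A `cov_network`.
#' @export
build_network <- function(cohort, fraction = 0.2,
                          method = c("pearson", "spearman")) {
  proportional_threshold(correlation_matrix(cohort, method = method),
                         fraction = fraction,
                         region_table = cohort$region_table)
}

#' Per-lobe mean correlation rate
#'
#' Mean pairwise correlation among each lobe's regions (both hemispheres
#' pooled, diagonal excluded). By default computed on the raw correlation
#' matrix; with `post_threshold = TRUE` only retained edges contribute
#' (absent pairs count as 0).
#'
#' @param mat a correlation matrix, or a `cov_network` when
#'   `post_threshold = TRUE`.
#' @param region_table a region table.
#' @param post_threshold average the thresholded weights instead of the
#'   raw correlations.
#' @return Named numeric vector, one mean per lobe.
#' @export
lobe_mean_correlation <- function(mat, region_table = dk_region_table(),
                                  post_threshold = FALSE) {
  if (inherits(mat, "cov_network")) {
    if (!post_threshold)
      stop("pass the raw correlation matrix for pre-threshold rates")
    mat <- mat$weights
  }
  lobes <- unique(region_table$lobe)
  out <- vapply(lobes, function(lb) {
    ids <- region_table$id[region_table$lobe == lb]
    sub <- mat[ids, ids]
    mean(sub[upper.tri(sub)])
  }, numeric(1))
  names(out) <- lobes
  out
}

#' Edge list of a covariance network
#'
#' @param network a `cov_network`.
#' @return data.frame with columns `region_a`, `region_b`, `weight`,
#'   ordered by weight descending.
#' @export
network_edge_list <- function(network) {
  stopifnot(inherits(network, "cov_network"))
  w <- network$weights
  ij <- which(upper.tri(w) & w != 0, arr.ind = TRUE)
  labs <- rownames(w)
  if (is.null(labs)) labs <- as.character(seq_len(nrow(w)))
  df <- data.frame(region_a = labs[ij[, 1]], region_b = labs[ij[, 2]],
                   weight = w[ij])
  df[order(-df$weight, df$region_a, df$region_b), , drop = FALSE]
}
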