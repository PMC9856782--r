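#' Cohen's d with pooled standard deviation
#'
#' Standardized mean difference (mean_a - mean_b) / s_pooled, pooling the
#' two sample variances with their n-1 weights.
#'
#' @param sample_a,sample_b numeric vectors with at least 2 values each.
#' @return The standardized mean difference; its sign matches the sign of
#'   `mean(sample_a) - mean(sample_b)`.
#' @export
cohens_d <- function(sample_a, sample_b) {
  if (length(sample_a) < 2L || length(sample_b) < 2L)
    stop("need at least 2 values per sample")
  na <- length(sample_a); nb <- length(sample_b)
  sp2 <- ((na - 1) * stats::var(sample_a) + (nb - 1) * stats::var(sample_b)) /
    (na + nb - 2)
  if (sp2 <= 0) stop("pooled standard deviation is zero; d is undefined")
  (mean(sample_a) - mean(sample_b)) / sqrt(sp2)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (monotone, clipped to `[0, 1]`),
#' delegating to [stats::p.adjust()] with `method = "BH"` after validating
#' the inputs.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same length and order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Region-wise two-sample comparison of FD values
#'
#' Per-region two-tailed two-sample t-test between two cohorts (Student,
#' equal variances, by default; set `var_equal = FALSE` for Welch),
#' Benjamini-Hochberg q-values across the 68 regions, and Cohen's d with
#' pooled SD. A region is flagged significant at raw `p < alpha`, the
#' selection rule the reference tables of this analysis style actually
#' reflect; the q column is always reported alongside for FDR-based
#' reading.
#'
#' @param cohort_a,cohort_b `fd_cohort` objects on the same region table,
#'   with at least 2 subjects each.
#' @param alpha significance level for the `significant` flag.
#' @param var_equal use the pooled-variance Student t (default) rather
#'   than Welch.
#' @return A data.frame of class `regional_comparison` with one row per
#'   region: group means and SDs, `t`, `p`, `q`, `d`, `significant`.
#' @export
regional_fd_tests <- function(cohort_a, cohort_b, alpha = 0.05,
                              var_equal = TRUE) {
  stopifnot(inherits(cohort_a, "fd_cohort"), inherits(cohort_b, "fd_cohort"))
  rt <- cohort_a$region_table
  if (!identical(rt$label, cohort_b$region_table$label))
    stop("cohorts are on different region tables")
  if (nrow(cohort_a$values) < 2L || nrow(cohort_b$values) < 2L)
    stop("need at least 2 subjects per cohort")
  n <- nrow(rt)
  out <- data.frame(region_id = rt$id, label = rt$label, lobe = rt$lobe,
                    hemisphere = rt$hemisphere,
                    mean_a = NA_real_, sd_a = NA_real_,
                    mean_b = NA_real_, sd_b = NA_real_,
                    t = NA_real_, p = NA_real_, d = NA_real_)
  for (j in seq_len(n)) {
    a <- cohort_a$values[, j]; b <- cohort_b$values[, j]
    if (stats::sd(a) == 0 && stats::sd(b) == 0)
      stop("degenerate variance in region ", rt$label[j])
    tt <- stats::t.test(a, b, var.equal = var_equal)
    out$mean_a[j] <- mean(a); out$sd_a[j] <- stats::sd(a)
    out$mean_b[j] <- mean(b); out$sd_b[j] <- stats::sd(b)
    out$t[j] <- unname(tt$statistic)
    out$p[j] <- tt$p.value
    out$d[j] <- cohens_d(a, b)
  }
  out$q <- bh_fdr(out$p)
  out$significant <- out$p < alpha
  class(out) <- c("regional_comparison", "data.frame")
  out
}

#' Subsample permutation test on network properties
#'
#' A group covariance network yields one value of each network property
#' per group, so group differences cannot be tested directly; this builds
#' an empirical null instead. Each iteration draws `subsample` subjects
#' from each cohort, pools the 2 x `subsample` subjects, re-splits them at
#' random into two pseudo-groups of `subsample`, builds each pseudo-group's
#' thresholded network, and records the pseudo-group difference in each
#' metric: modularity Q (of the detected partition), mean participation
#' coefficient, mean within-module degree z-score, and mean within-lobe
#' retained weight. The observed full-group differences are then compared
#' one-tailed (direction taken from the observed sign) against the null,
#' with BH correction across the metrics. Deterministic given `seed`.
#'
#' @param cohort_a,cohort_b `fd_cohort` objects with at least `subsample`
#'   subjects each.
#' @param n_perm number of permutation iterations (1000 in the full
#'   analysis).
#' @param subsample subjects drawn per group per iteration.
#' @param fraction proportional threshold for every network built.
#' @param alpha nominal level for the significance decisions.
#' @param seed master seed; all subsampling, re-splitting and module
#'   detection derive from it.
#' @return An object of class `permutation_result`: `metrics` data.frame
#'   (observed per group, observed difference, 95th-percentile critical
#'   value of the directed null, `p`, `q`, `significant`), `null` matrix
#'   of per-iteration pseudo-group differences (n_perm x metrics),
#'   `n_perm`, `subsample`, `seed`.
#' @export
permutation_network_test <- function(cohort_a, cohort_b, n_perm = 1000L,
                                     subsample = 10L, fraction = 0.2,
                                     alpha = 0.05, seed = 1L) {
  stopifnot(inherits(cohort_a, "fd_cohort"), inherits(cohort_b, "fd_cohort"))
  n_perm <- check_count(n_perm, "n_perm")
  subsample <- check_count(subsample, "subsample")
  na <- nrow(cohort_a$values); nb <- nrow(cohort_b$values)
  if (subsample > na || subsample > nb)
    stop("subsample (", subsample, ") exceeds a cohort size")
  rt <- cohort_a$region_table

  metric_names <- c("modularity_q", "mean_participation",
                    "mean_within_module_z", "mean_intra_lobe_weight")
  lobe_ids <- lapply(unique(rt$lobe), function(lb) rt$id[rt$lobe == lb])
  net_metrics <- function(values, part_seed) {
    net <- proportional_threshold(stats::cor(values), fraction = fraction,
                                  region_table = rt)
    if (net$n_edges < 1L) return(c(0, 0, 0, 0))
    part <- detect_modules(net, seed = part_seed, restarts = 3L)
    intra <- vapply(lobe_ids, function(ids) {
      sub <- net$weights[ids, ids]
      ww <- sub[upper.tri(sub)]
      ww <- ww[ww != 0]
      if (length(ww)) mean(ww) else 0
    }, numeric(1))
    c(part$q,
      mean(participation_coefficient(net, part)),
      mean(within_module_degree_z(net, part)),
      mean(intra))
  }

  res <- withr::with_seed(as.integer(seed), {
    part_seeds <- sample.int(.Machine$integer.max, n_perm + 1L)
    # one shared seed for both observed networks keeps the comparison
    # symmetric under swapping the cohort labels
    obs_a <- net_metrics(cohort_a$values, part_seeds[n_perm + 1L])
    obs_b <- net_metrics(cohort_b$values, part_seeds[n_perm + 1L])
    null <- matrix(NA_real_, n_perm, length(metric_names),
                   dimnames = list(NULL, metric_names))
    for (i in seq_len(n_perm)) {
      ia <- sample.int(na, subsample)
      ib <- sample.int(nb, subsample)
      pool <- rbind(cohort_a$values[ia, , drop = FALSE],
                    cohort_b$values[ib, , drop = FALSE])
      split1 <- sample.int(2L * subsample, subsample)
      m1 <- net_metrics(pool[split1, , drop = FALSE], part_seeds[i])
      m2 <- net_metrics(pool[-split1, , drop = FALSE], part_seeds[i])
      null[i, ] <- m1 - m2
    }
    list(obs_a = obs_a, obs_b = obs_b, null = null)
  })

  obs_diff <- res$obs_a - res$obs_b
  direction <- ifelse(obs_diff >= 0, 1, -1)
  # ties at floating-point resolution count as exceedances, so a metric
  # that is constant by construction (e.g. mean Z, identically 0) yields
  # p = 1 rather than an artifact of rounding noise
  p <- vapply(seq_along(metric_names), function(k) {
    directed_null <- direction[k] * res$null[, k]
    (1 + sum(directed_null >= direction[k] * obs_diff[k] - 1e-10)) /
      (n_perm + 1)
  }, numeric(1))
  critical <- vapply(seq_along(metric_names), function(k)
    unname(stats::quantile(direction[k] * res$null[, k], 0.95, type = 7)),
    numeric(1))
  q <- bh_fdr(p)
  metrics <- data.frame(metric = metric_names,
                        observed_a = res$obs_a, observed_b = res$obs_b,
                        observed_diff = obs_diff,
                        critical_95 = direction * critical,
                        p = p, q = q, significant = q < alpha)
  structure(list(metrics = metrics, null = res$null, n_perm = n_perm,
                 subsample = subsample, fraction = fraction,
                 alpha = alpha, seed = as.integer(seed)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> %d iterations, subsample %d per group\n",
              x$n_perm, x$subsample))
  print(x$metrics[, c("metric", "observed_a", "observed_b", "p", "q",
                      "significant")], row.names = FALSE)
  invisible(x)
}
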