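#' Pipeline configuration
#'
#' Collects every tunable the pipeline uses, with the canonical defaults:
#' box sizes 10 down to 2 with a minimum fitting window of 4 points,
#' proportional threshold 0.2, Pearson correlation, weight-mode
#' intra-lobular connectivity, 1000 permutations with subsamples of 10,
#' alpha 0.05. Validates ranges and round-trips through JSON/YAML as a
#' plain named list.
#'
#' @param r_max,r_min,min_window FD estimation schedule, see
#'   [boxcount_series()] and [fit_fd()].
#' @param threshold_fraction see [proportional_threshold()].
#' @param correlation_method `"pearson"` or `"spearman"`.
#' @param intra_mode `"weight"` or `"literal"`, see [lobe_connectivity()].
#' @param n_perm,subsample,alpha see [permutation_network_test()].
#' @param seed master seed for all stochastic stages.
#' @return A validated named list of class `pipeline_config`.
#' @export
pipeline_config <- function(r_max = 10L, r_min = 2L, min_window = 4L,
                            threshold_fraction = 0.2,
                            correlation_method = "pearson",
                            intra_mode = "weight",
                            n_perm = 1000L, subsample = 10L,
                            alpha = 0.05, seed = 1L) {
  cfg <- list(r_max = check_count(r_max, "r_max"),
              r_min = check_count(r_min, "r_min"),
              min_window = check_count(min_window, "min_window"),
              threshold_fraction = threshold_fraction,
              correlation_method = match.arg(correlation_method,
                                             c("pearson", "spearman")),
              intra_mode = match.arg(intra_mode, c("weight", "literal")),
              n_perm = check_count(n_perm, "n_perm"),
              subsample = check_count(subsample, "subsample"),
              alpha = alpha,
              seed = as.integer(seed))
  if (cfg$r_max < cfg$r_min) stop("r_max must be >= r_min")
  if (cfg$threshold_fraction <= 0 || cfg$threshold_fraction > 1)
    stop("threshold_fraction must be in (0, 1]")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must be in (0, 1)")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full two-group comparison pipeline on FD cohorts
#'
#' From two cohort FD matrices: regional t/FDR/effect-size comparison,
#' group covariance networks with proportional thresholding, module
#' detection, node metrics, lobe connectivity (intra/inter) with ratios,
#' within-lobe link counts, and (optionally) the subsample permutation
#' test on network properties.
#'
#' @param cohort_a,cohort_b `fd_cohort` objects (reference group first).
#' @param config a [pipeline_config()].
#' @param permutation run the permutation stage (the slowest stage).
#' @return A named list of stage results of class `pipeline_result`.
#' @export
run_pipeline <- function(cohort_a, cohort_b, config = pipeline_config(),
                         permutation = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  regional <- regional_fd_tests(cohort_a, cohort_b, alpha = config$alpha)
  net_a <- build_network(cohort_a, fraction = config$threshold_fraction,
                         method = config$correlation_method)
  net_b <- build_network(cohort_b, fraction = config$threshold_fraction,
                         method = config$correlation_method)
  part_a <- detect_modules(net_a, seed = config$seed)
  part_b <- detect_modules(net_b, seed = config$seed + 1L)
  lobe_a <- lobe_connectivity(net_a, mode = config$intra_mode)
  lobe_b <- lobe_connectivity(net_b, mode = config$intra_mode)
  result <- list(
    config = config,
    groups = c(cohort_a$group_label, cohort_b$group_label),
    regional = regional,
    network_a = net_a, network_b = net_b,
    partition_a = part_a, partition_b = part_b,
    modules_a = partition_table(part_a, cohort_a$region_table),
    modules_b = partition_table(part_b, cohort_b$region_table),
    nodes_a = node_metrics(net_a, part_a),
    nodes_b = node_metrics(net_b, part_b),
    lobe_a = lobe_a, lobe_b = lobe_b,
    intra_ratio = connectivity_ratio(lobe_a, lobe_b, "intra", zero = "na"),
    inter_ratio = connectivity_ratio(lobe_a, lobe_b, "inter", zero = "na"),
    links_a = link_counts(net_a),
    links_b = link_counts(net_b),
    lobe_corr_a = lobe_mean_correlation(correlation_matrix(cohort_a),
                                        cohort_a$region_table),
    lobe_corr_b = lobe_mean_correlation(correlation_matrix(cohort_b),
                                        cohort_b$region_table),
    permutation = NULL)
  if (permutation)
    result$permutation <- permutation_network_test(
      cohort_a, cohort_b, n_perm = config$n_perm,
      subsample = config$subsample, fraction = config$threshold_fraction,
      alpha = config$alpha, seed = config$seed + 2L)
  class(result) <- "pipeline_result"
  result
}

#' Render a pipeline result as a plain-text report
#'
#' One human-readable document: significant regions of the regional
#' comparison, module listings (largest module first), within-lobe link
#' counts, and the intra-/inter-lobular connectivity tables with
#' group-B/group-A ratios. The permutation section is included only when
#' that stage was run.
#'
#' @param result a `pipeline_result` from [run_pipeline()].
#' @param path optional file to write the report to.
#' @return The report as a character vector of lines, invisibly if `path`
#'   is given.
#' @export
render_report <- function(result, path = NULL) {
  stopifnot(inherits(result, "pipeline_result"))
  ga <- result$groups[1]; gb <- result$groups[2]
  fmt_tbl <- function(df) utils::capture.output(print(df, row.names = FALSE))
  lines <- c(
    "FD covariance network comparison report",
    sprintf("groups: %s (reference) vs %s", ga, gb),
    sprintf("threshold fraction %.3g | correlation %s | seed %d",
            result$config$threshold_fraction,
            result$config$correlation_method, result$config$seed),
    "",
    sprintf("== Regional FD comparison (%d of 68 regions significant at p < %.2g) ==",
            sum(result$regional$significant), result$config$alpha),
    fmt_tbl(format(result$regional[result$regional$significant,
                                   c("label", "lobe", "mean_a", "sd_a",
                                     "mean_b", "sd_b", "p", "q", "d")],
                   digits = 4)),
    "",
    sprintf("== Modules: %s %d (Q = %.4f) | %s %d (Q = %.4f) ==",
            ga, result$partition_a$n_modules, result$partition_a$q,
            gb, result$partition_b$n_modules, result$partition_b$q),
    sprintf("%s module sizes: %s", ga,
            paste(result$partition_a$module_sizes, collapse = "/")),
    sprintf("%s module sizes: %s", gb,
            paste(result$partition_b$module_sizes, collapse = "/")),
    "",
    sprintf("== Within-lobe link counts (L/R/B), %s then %s ==", ga, gb),
    fmt_tbl(result$links_a), fmt_tbl(result$links_b),
    "",
    "== Intra-lobular connectivity ==",
    fmt_tbl(data.frame(lobe = result$lobe_a$lobe,
                       a = signif(result$lobe_a$intra, 4),
                       b = signif(result$lobe_b$intra, 4),
                       ratio_pct = signif(result$intra_ratio, 4))),
    "",
    "== Inter-lobular connectivity ==",
    fmt_tbl(data.frame(lobe = result$lobe_a$lobe,
                       a = signif(result$lobe_a$inter, 4),
                       b = signif(result$lobe_b$inter, 4),
                       ratio_pct = signif(result$inter_ratio, 4))))
  if (!is.null(result$permutation)) {
    lines <- c(lines, "",
               sprintf("== Permutation test (%d iterations, subsample %d) ==",
                       result$permutation$n_perm, result$permutation$subsample),
               fmt_tbl(format(result$permutation$metrics, digits = 4)))
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
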