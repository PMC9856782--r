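#!/usr/bin/env Rscript
# Stage 7: assemble the full pipeline report in one pass.
#
# Re-runs every stage through run_pipeline() (a shorter permutation run
# than stage 6, for a self-contained document) and renders the combined
# plain-text report.

suppressPackageStartupMessages(library(fdcovnet))

control <- read_cohort("results/02_cohort_control.csv", "control")
mci <- read_cohort("results/02_cohort_mci.csv", "mci")

cfg <- pipeline_config(n_perm = 200L, subsample = 10L, seed = 20230103L)
res <- run_pipeline(control, mci, cfg)
report <- render_report(res, "results/07_report.txt")
cat(report, sep = "\n")
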