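---
title: "Methods: fractal-dimension structural covariance networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fractal-dimension structural covariance networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdcovnet)
```

fdcovnet implements a morphometric network pipeline for the cerebral
cortex: per-region fractal dimension (FD) by 3D box counting, group-level
FD covariance networks, modular decomposition, and lobe-level connectivity
comparison between two groups. This vignette documents the model choices,
the tunable parameters, and the numerical conventions, so that results are
interpretable and reproducible without reading the source.

## Box-counting fractal dimension

The FD of a voxelized object follows the power law N(r) ~ r^-FD, where
N(r) is the number of cubes of side r (in voxels) needed to cover the
object. Taking base-2 logarithms turns this into the line

    log2 N(r) = FD * log2(1/r) + k,

so FD is a regression slope. `count_boxes()` tiles the volume with
grid-aligned cubes anchored at the array origin; partial boxes at the far
faces are counted when occupied, so the tiling always covers the object.
No offset or orientation search is performed — the box grid is fixed,
which is the simplest reading of side-by-side stacking and keeps counts
deterministic.

`boxcount_series()` runs the schedule r = 10, 9, ..., 2 (nine points).
`fit_fd()` then searches every contiguous window of at least
`min_window = 4` points and keeps the one maximizing the squared
correlation R² between log2 N and log2(1/r); the FD estimate is that
window's least-squares slope. The window search is what makes the
estimate robust to the flattening that occurs when boxes become larger
than the object (left end) or approach voxel size (right end). Ties on R²
(within 1e-12) prefer the longer window, then the window containing the
larger boxes; a window with constant counts gets R² = 0 so it can never
shadow an informative window. With four or more points per window, a
nine-point series yields 21 candidate windows — an exhaustive scan is
cheap and exact.

Because no public ground truth exists for cortical FD, the estimator is
validated on phantoms whose dimension is known analytically: a solid cube
(FD 3), a one-voxel slab (FD 2), and the level-4 Menger sponge
(FD = log 20 / log 3 ≈ 2.7268, filled-voxel count exactly 20^4). At side
64 the cube recovers 2.950, the slab 1.967, and the sponge 2.812 —
within 0.05, 0.1 and 0.15 of truth respectively. The residual bias is the
discretization error of a fixed nine-point schedule on finite grids; it
shrinks with object size and is shared by any box-counting implementation
with this schedule.

`region_fd()` extracts one label from a parcellation, crops it to its
bounding box, and applies the same estimator. Cropping makes the count
object-relative rather than field-of-view-relative; the full-grid variant
is exposed via `crop = FALSE` for sensitivity checks, since published
descriptions of regional FD rarely state which convention was used.

## The region table

All matrices are indexed by the 68-region rearranged Desikan–Killiany
table returned by `dk_region_table()`: frontal ids 1–28, temporal 29–46,
parietal 47–60, occipital 61–68; odd ids left hemisphere, even ids right.
The insula is housed in the frontal block, as in the source numbering.
This ordering fixes row/column order of every correlation matrix,
network, and report downstream.

## Covariance networks

`correlation_matrix()` computes the Pearson correlation of FD values
between every pair of regions across the subjects of one group — the
structural covariance map. Pearson is the structural-covariance default;
Spearman is available via `method`. No covariate adjustment is applied
before correlating.

`proportional_threshold()` keeps the strongest fraction (default 0.2) of
the 68·67/2 = 2278 unique region pairs: the top floor(0.2 × 2278) = 455
coefficients, provided they are strictly positive — negative correlations
and the diagonal are always zeroed, and fewer edges are kept if positive
pairs run out. Ties at the cutoff are broken by value descending and then
by (row, column) order, so the edge set is a deterministic function of
the matrix. Both the weighted matrix (used by modularity) and the binary
adjacency (used by degree-based metrics) are carried on every network.
Proportional thresholding is idempotent and invariant under strictly
monotone transforms of the positive weights; both properties are tested.

## Modularity and module detection

`modularity_q()` evaluates Newman's quality function on the weighted
retained matrix,

    Q = (1/2m) * sum_ij [A_ij - k_i k_j / 2m] * delta(c_i, c_j),

with k_i the weighted degree and 2m the total weight. The single-module
partition telescopes to exactly 0, and two disconnected unit triangles
under their natural split give exactly 0.5 — both serve as closed-form
anchors in the tests, alongside a cross-check against igraph's
implementation on 0/1 graphs.

`detect_modules()` maximizes Q by greedy multi-level (Louvain) sweeps.
A single greedy sweep is order-dependent and can land in a local optimum,
so the sweep is restarted (default 10 times) with different node orders
under one master seed and the best-Q partition kept; on every graph small
enough to enumerate, restarts bring the result to within 0.05 of the
exact optimum found by `brute_force_modules()`, and exactly to it on
disconnected-clique constructions. Partitions are relabeled so module 1
is the largest, with ties broken by smallest member id — the convention
used when listing modules in reports.

## Node and lobe connectivity

On the binary adjacency, with a partition in hand:

* within-module degree z-score: Z_i = (K_i − mean K)/sd K, where K_i
  counts links of node i inside its own module and mean/sd are taken over
  that module's nodes with the population (no n−1) normalization, as the
  defining formula has no finite-sample correction. A module whose
  within-degrees have zero spread (including singletons) gets Z = 0 by
  convention.
* participation coefficient: P_i = 1 − Σ_c (K_ci/K_i)², with K_ci the
  links of node i into module c. P is 0 for a provincial node and
  approaches 1 − 1/n_modules at uniform spread; isolated nodes get P = 0.

`lobe_connectivity()` replays these with the four anatomical lobes
(hemispheres pooled) as the partition. The inter-lobular connectivity of
a lobe is the mean P of its nodes. For the intra-lobular side there are
two candidate readings, and the package computes both: the literal
per-lobe mean of Z — which is identically 0 whenever the lobe's degree
spread is nonzero, because z-scores average to zero over the module that
defines them — and the mean retained edge weight among within-lobe edges.
The weight reading is the headline (`mode = "weight"`) precisely because
the literal reading is degenerate by construction yet published
intra-lobular connectivity tables contain nonzero values; the aggregation
those tables used cannot be recovered from their text, so neither reading
is claimed to reproduce them. `link_counts()` splits each lobe's edges
into left-lateral, right-lateral and bilateral, and
`connectivity_ratio()` expresses a comparison group as a percentage of
the reference group per lobe.

## Group comparison

`regional_fd_tests()` runs a two-tailed two-sample t-test per region
(Student with pooled variance by default; Welch via `var_equal = FALSE`),
Benjamini–Hochberg q-values across the 68 regions, and Cohen's d with
pooled SD. Regions are flagged significant at raw p < alpha; q is always
reported alongside. The flag deliberately follows the uncorrected
p-value: reference tables in this literature list "significant" regions
whose printed p-values (up to ≈0.044 among 68 tests) could not survive a
BH threshold of 0.05, so the raw-p rule is the one that reproduces the
shape of such tables, while the q column supports the stricter reading.

A thresholded group network yields exactly one value of each network
property per group, so group differences need an empirical null.
`permutation_network_test()` builds it by subsampling: each iteration
draws 10 subjects per group, pools the 20, re-splits them at random into
two pseudo-groups, rebuilds each pseudo-group's network from scratch, and
records the pseudo-group difference in each metric — modularity Q of the
detected partition, mean P, mean Z, and mean within-lobe retained weight.
(Mean Z is kept for completeness although it is 0 by construction; its
difference is treated as a tie, never as evidence.) After `n_perm`
iterations (default 1000) the observed full-group differences are
compared one-tailed — direction taken from the observed sign — against
the null, with the add-one estimate p = (1 + #{null ≥ observed})/(n_perm
+ 1), the empirical 95th percentile as critical value, and BH correction
across the metrics.

Two calibration facts shape how this test should be read. First, when the
observed groups are larger than the subsample (30 vs 10), the null
differences are noisier than the observed difference, which makes the
test conservative — a property inherent to the subsample construction,
not a defect of the implementation. Second, when the subsample equals the
group size the construction reduces to a plain permutation test and is
exact; the type-I calibration simulation in the test suite therefore uses
groups of 10 with subsample 10, where the nominal level is the right
yardstick, and observes rejection rates within [0.02, 0.10] at nominal
0.05.

## The cohort simulator

No imaging data ship with the package; every downstream stage is
exercised on simulated cohorts with planted structure. `simulation_spec()`
defines the generative model: subjects are iid draws from a
68-dimensional normal with per-region means and SDs and a block-constant
correlation matrix — `rho_within` inside each planted block,
`rho_between` across blocks — checked for positive definiteness at
construction. `simulate_two_groups()` draws group A unchanged and group B
independently (distinct sub-seed, master seed + 1) with the means of the
effect regions lowered by `effect_d` region-SDs.

The defaults are the study conditions the package emulates, chosen once:
30 subjects per group; region means equal to the control lobe-level FD
values (2.1985–2.2990); per-region SD 0.04, the mid-range of published
per-region spreads (≈0.017–0.078); the four lobes as planted blocks with
rho 0.5 within and 0.1 between, reflecting that intra-lobe covariance
exceeds inter-lobe covariance; and a planted reduction of d = 0.3
(approximately the mean of the published per-region effect sizes) in the
27 regions reported as atrophied in mild cognitive impairment. Under
these defaults the two groups share one covariance structure, so regional
tests should fire while network-level comparisons should be null — the
analysis scripts show exactly that, and demonstrate the detection
direction separately with a weakened-correlation (rho_within 0.25) group,
whose intra-lobular ratios drop to roughly 68–86% of the reference.

What the simulator does not emulate: raw T1 images, segmentation and
parcellation error, spatial autocorrelation beyond the block structure,
covariate structure (age, sex), site effects, or non-Gaussian tails.
Passing tests therefore demonstrate that the machinery is correct and
calibrated under a known generative model, not that any particular
clinical effect is reproducible from real MRI.

## Determinism and problem sizes

Every stochastic stage takes a seed; sub-seeds (per group, per
permutation iteration, per restart) are derived deterministically from
it, so all artifacts are byte-identical across runs with equal seeds —
this is itself a tested property. The test suite scales simulations to
desk size: planted-recovery runs use 200 subjects, power and FDR
calibration use 200 and 100 replicates at n = 30, and the permutation
calibration uses 100 replicates of 200 iterations. The analysis scripts
run the full 1000-iteration permutation on the 30 + 30 default cohorts.

## Known limitations

* Box counting uses a single fixed grid anchor; offset-averaged or
  rotation-averaged variants would smooth N(r) but change the estimator.
* FD values depend on the r-schedule and window rule; comparisons are
  meaningful within one configuration, not across configurations.
* The block-normal covariance model is a stand-in for whatever process
  generates inter-subject FD covariance in real cohorts.
* Louvain restarts make local-optimum artifacts rare but cannot
  guarantee the global optimum on large graphs.
* The permutation test is conservative whenever the subsample is smaller
  than the groups, and its mean-Z metric is degenerate by construction.
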