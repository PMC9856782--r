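# fdcovnet

Cortical atrophy in early neurodegeneration (e.g. mild cognitive
impairment, the prodromal stage of Alzheimer's disease) changes not only
the volume of cortical regions but the *shape complexity* of their folded
surface. fdcovnet is an R package for quantifying that change and its
network-level consequences:

1. **Fractal dimension (FD) morphometry** — each cortical region,
   extracted from a 68-region Desikan–Killiany parcellation volume, is
   reduced to one number by 3D box counting: cover the region with cubes
   of side r = 10…2 voxels, count occupied cubes N(r), and estimate FD as
   the slope of log₂N(r) on log₂(1/r) over the contiguous window (≥ 4
   points) with the highest R². Lower FD = less convoluted cortex.
2. **Structural covariance networks** — within a group, FD values of
   region pairs are correlated across subjects; keeping the strongest 20%
   of the 2278 region pairs (455 positive edges) yields a 68-node brain
   network per group.
3. **Network comparison** — modularity Q (Newman's formulation on the
   weighted network) with Louvain module detection, within-module degree
   z-score Zᵢ and participation coefficient Pᵢ, lobe-level intra-/
   inter-lobular connectivity with patient/control ratios, per-region
   t-tests with Benjamini–Hochberg FDR and Cohen's d, and a
   subsample-permutation test (draw 10 + 10 subjects, pool, re-split,
   rebuild networks, 1000 iterations) for group differences in network
   properties.

Because cohort MRI data are typically private, the package ships
first-class synthetic data: voxel phantoms of known dimension (solid
cube FD = 3, slab FD = 2, Menger sponge FD = log20/log3 ≈ 2.727) that
validate the estimator, and a two-group cohort simulator with planted
covariance blocks and planted regional effects that exercises every
downstream stage with known ground truth.

Audience: researchers in structural neuroimaging / brain-network
morphometry, and anyone needing a tested, deterministic reference
implementation of box-counting FD and proportional-threshold covariance
networks.

## Worked example

```r
library(fdcovnet)

# 1. the estimator on a phantom with known dimension
fit <- fit_fd(boxcount_series(make_menger_sponge(4)))
fit
#> <fd_fit> FD = 2.8125 (R^2 = 0.9871, window r = 7..4)
#  truth: log(20)/log(3) = 2.7268

# 2. simulate the default two-group study: 30 + 30 subjects, 68 regions,
#    lobe-structured covariance, planted FD reduction (d = 0.3) in 27 regions
groups <- simulate_two_groups(simulation_spec())

# 3. regional comparison
res <- regional_fd_tests(groups$a, groups$b)
sum(res$significant)
#> [1] 28

# 4. group networks and modules
net <- build_network(groups$a)         # 455 edges kept of 2278 pairs
part <- detect_modules(net, seed = 1)
part
#> <module_partition> 4 modules (sizes 28/18/14/8), Q = 0.5324
```

The detected modules are exactly the four planted lobe blocks (frontal
28, temporal 18, parietal 14, occipital 8), and Q ≈ 0.53 reflects the
strong planted within-lobe correlation (0.5 within vs 0.1 between). In
the regional table, 28 regions are flagged at p < 0.05 against 27
planted — the pipeline recovers the planted atrophy pattern with roughly
one false positive at this seed.

## The analysis workflow

Numbered scripts under `analysis/` run the full study on simulated
cohorts and write tables under `results/`:

| script | what it does |
|---|---|
| `01_phantom_validation.R` | FD recovery on cube / slab / Menger phantoms |
| `02_simulate_cohorts.R` | simulate the two 30-subject groups, write CSVs |
| `03_regional_comparison.R` | per-region t / FDR / effect-size table |
| `04_networks_and_modules.R` | correlation maps, 20%-threshold networks, Louvain modules |
| `05_lobe_connectivity.R` | intra-/inter-lobular connectivity, ratios, link counts |
| `06_permutation_test.R` | 1000-iteration subsample permutation test |
| `07_report.R` | combined plain-text report |

Run them in order from the repository root, e.g.
`for s in analysis/0*.R; do Rscript $s; done`.

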