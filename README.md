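# tpllsubtyper

Molecular subgroup discovery and characterization for T-cell
prolymphocytic leukemia (T-PLL) expression cohorts.

T-PLL is a rare, aggressive mature T-cell leukemia. Cohorts are small
(tens of patients), profiling is typically array-based, and the central
analytical questions are: do the tumor expression profiles split into
reproducible molecular subgroups, how do those subgroups differ from
normal T-cells and from each other, and do the differences extend to copy
number, regulatory networks, external cohorts and survival?
`tpllsubtyper` packages that complete analysis chain for R users working
with log2-scale genes-x-samples expression matrices, and bundles a
synthetic-cohort generator with planted ground truth so every stage can be
exercised and tested without patient data.

## What it computes

* **Subgroup discovery** — hierarchical clustering of samples with the
  correlation distance `d(i,j) = 1 − r(i,j)` and Ward linkage
  (`ward.D2`); explicit `k`-cluster cuts with reproducible labels.
* **Cluster stability** — multiscale-bootstrap support per dendrogram
  node: recovery frequencies `BP_τ` across gene-resampling scales τ are
  probit-extrapolated via `qnorm(1−BP_τ) = v√τ + c/√τ` to the
  approximately unbiased support `AU = 1 − Φ(v − c)`; and
  patient-removal stability: remove 1–10 tumor samples, recluster, pair
  clusters by majority overlap, and score the fraction of correctly
  re-assigned samples.
* **Differential expression** — per-gene one-way group models (control
  baseline), empirical-Bayes variance moderation
  `s̃² = (d₀s₀² + d s²)/(d₀ + d)`, moderated t with `d₀ + d` df, BH
  q-values, and three-set Venn overlaps of the subgroup DE sets.
* **Enrichment** — direction-stratified one-sided Fisher tests of DE sets
  against GMT catalogs over the measured-gene background, BH-adjusted
  within annotation families.
* **Copy number** — circular binary segmentation of probe log2-ratios
  (permutation split test, C++ kernel), gene-level assignment by segment
  midpoint lookup, per-subgroup median profiles and recurrent-alteration
  frequencies.
* **Regulatory networks** — per-gene lasso models (own copy number +
  other genes' expression) with covariance-test significance
  `p = exp(−T_k)` for entering predictors, repeated over 100 random
  two-thirds training subsets; consensus links (support ≥ 75/100 at link
  q ≤ 0.01), module extraction (≥ 2 links within a module of ≥ 3 genes),
  and held-out prediction quality versus degree-preserving null networks.
* **Cohort transfer** — parametric empirical-Bayes batch adjustment of a
  new cohort onto the reference, then nearest-positive-correlation label
  assignment with confidence flags.
* **Survival** — Kaplan–Meier curves and log-rank tests across subgroups
  and sexes.

## Worked example

A full synthetic cohort (10 controls, 18/11/39 tumor samples in three
planted subgroups, 2,000 genes) and the first analysis stages:

```r
library(tpllsubtyper)

cohort <- generate_cohort(simulation_config(), seed = 1)
tree <- ward_cluster(correlation_distance(cohort$expr))
subgroups <- cut_tree(tree, k = 4)
table(cluster = subgroups, truth = cohort$truth$labels[names(subgroups)])
#>        truth
#> cluster control SG1 SG2 SG3
#>       1      10   0   0   0
#>       2       0  18   0   0
#>       3       0   0  11   0
#>       4       0   0   0  39
```

The four clusters coincide exactly with the planted groups. Stability
under removal of ten tumor patients (100 replicates):

```r
stab <- removal_stability(cohort$expr, subgroups,
  tumor_ids = subset(cohort$samples, group != "control")$sample_id,
  n_remove = 10, n_reps = 100, seed = 2)
stab$median
#> [1] 1
```

Every replicate re-assigns all retained samples to their original
subgroup. Differential expression against the controls at `q ≤ 0.05`:

```r
de <- run_diffexpr(cohort$expr, cohort$samples, q_cutoff = 0.05)
vapply(de$de_sets, length, 1L)
#> SG1 SG2 SG3
#> 425 498 528
de_overlaps(de)$combined
#> a_only b_only c_only     ab     ac     bc    abc  union
#>    109    103    125      4     12     91    300    744
```

SG2 and SG3 share many more altered genes with each other (`bc` = 91)
than either shares with SG1 (4 and 12), reflecting the planted hierarchy
in which SG2 and SG3 are mutually closer. A clinical contingency check —
are pretreated patients distributed evenly across the subgroups? — uses
the exact r×c Fisher test:

```r
pre <- table(cohort$samples$group, cohort$samples$pretreated)[-1, ]
fisher_exact_rxc(pre)
#> Fisher exact (r x c enumeration): statistic = 0.04897719, p = 0.49813
```

and the simulated sex-dependent survival difference is picked up by the
log-rank test:

```r
tum <- subset(cohort$samples, group != "control" & !is.na(time_days))
logrank_test(tum$time_days, tum$status, tum$sex)
#> log-rank: statistic = 13.41579, p = 0.00024951
```

`run_all(run_config(), out_dir = "run1", seed = 1)` executes the whole
chain — including copy-number segmentation and the 100-run network
ensemble — and writes TSV outputs plus a JSON manifest; see the methods
vignette (`vignettes/methods.Rmd`) for the models, parameter defaults and
design decisions behind each stage.

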