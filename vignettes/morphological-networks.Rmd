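---
title: "Individual morphological similarity networks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual morphological similarity networks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(morphnet)
```

## The problem

Most structural-MRI network methods either require diffusion imaging
(tractography) or pool subjects into a single group-level covariance
matrix, losing individual differences. morphnet implements a
single-subject alternative: two cortical parcels are considered connected
to the extent that their *distributions* of vertex-wise morphometry
(cortical volume, surface area, or thickness) look alike. The resulting
per-subject networks can then be summarized by graph efficiency and
related to behavior, here with an explicit test of whether the
efficiency–behavior association changes with age.

## The network model

For one subject and one measure, each cortical parcel contributes the
multiset of its vertex values. For every pair of parcels:

1. the pooled value range `[min, max]` over the union of both parcels is
   divided into `n_bins` (default 30) equal-width bins — a shared axis is
   what makes two frequency vectors comparable;
2. each parcel's vertex frequencies over those bins form a histogram;
3. the edge weight is the Pearson correlation of the two frequency
   vectors.

This yields a `P x P` symmetric similarity matrix with unit diagonal
(`build_similarity_matrix()`). Parcels with fewer than `min_vertices`
(default 50) vertices are excluded beforehand (`filter_parcels()`);
with the default 51-region functional parcellation this leaves the 32
parcels of `yeo32_parcellation()`.

Because negative similarities (inhibition-like relations) still carry
topological information, filtering operates on `|s|`
(`absolutize()`). The orthogonal-minimal-spanning-tree procedure
(`omst_select()`) then extracts the strongest connections without an
arbitrary density threshold: round *m* adds the maximum spanning tree
that is edge-disjoint from all previous rounds, and the retained union is
the round maximizing global-cost-efficiency,
`GCE(m) = GE_w(union) - Cost(m)`, where `Cost(m)` is the selected weight
mass as a fraction of total weight. The union at the optimum is
binarized; all efficiency metrics are computed on this binary graph.

Efficiency (`global_efficiency()`, `nodal_efficiency()`,
`local_efficiency()`) uses inverse shortest-path lengths with
`1/Inf := 0`: global efficiency is the mean over ordered pairs, nodal
efficiency the per-node mean, and local efficiency the global efficiency
of the subgraph induced on a node's neighbors (the node itself
excluded).

## The statistical model

For a behavior score and an efficiency value (global, or one parcel's
nodal/local efficiency), `interaction_glm()` fits by ordinary least
squares

    beh = a1*age + a2*E + a3*sex + a4*edu + a5*ICV + a6*morph
          + beta*(age x E) + intercept + error

where `morph` is the whole-cortex covariate matched to the network
measure: total cortical volume for the volume network, total surface
area for the area network, mean thickness (the unweighted mean over all
retained vertices, not the mean of parcel means) for the thickness
network. `beta` is the quantity of interest: a nonzero value means the
efficiency–behavior association differs between younger and older
subjects.

`efficiency_interaction_scan()` applies the model across metrics and
behaviors, controls the false discovery rate per family with
Benjamini–Hochberg at `q < 0.05`, and attaches leave-one-out
reproducibility (`loo_reproducibility()`): the model is refitted once
per subject with that subject removed, and reproducibility is the
percentage of folds in which `beta` stays significant.

```{r example}
spec <- cohort_spec(seed = 1)
study <- simulate_cohort(spec, measure = "area")
fit <- interaction_glm(study$cohort, "cognitive", "e_glob")
summary(fit)
plot(fit)               # age-group scatter with per-group slopes
loo_reproducibility(study$cohort, "cognitive", "e_glob")
```

## Tunable parameters

| parameter | default | units | notes |
|---|---|---|---|
| `n_bins` | 30 | bins | histogram resolution; similarity of identical multisets is 1 for any value |
| `min_vertices` | 50 | vertices | parcels with fewer are excluded (strictly `< 50` removed) |
| `distance` (OMST) | `"inverse"` | — | edge distance `1/w` inside the GCE criterion; `"one-minus"` (`1 - w`) available |
| `max_rounds` (OMST) | `N - 1` | rounds | cap on orthogonal trees; argmax is over all completed rounds |
| `standardize` | `"all"` | — | z-score behavior and continuous predictors; `"predictors"` / `"none"` for raw scales |
| `q_threshold` | 0.05 | — | BH-FDR threshold per family |
| `loo_alpha` | 0.05 | — | per-fold, uncorrected significance level on `beta` |
| `age_split` | 35 | years | only for the exported subgroup scatters; the model uses continuous age |

## Numerical and design choices

* **Binning convention.** Bins are left-closed/right-open, with a closed
  final bin, so every pooled value lands in exactly one bin and counts
  conserve multiset sizes exactly.
* **Counts vs proportions.** Raw counts are correlated; Pearson's
  location/scale invariance makes the choice immaterial, which the test
  suite asserts as a property.
* **Degenerate pairs.** A zero-width pooled range or a zero-variance
  frequency vector gives similarity 0 with a classed warning (counted in
  the matrix metadata) instead of dropping the pair: 0 is neutral after
  absolutization and OMST filtering, and the matrix stays complete.
* **OMST determinism.** Spanning trees are built by Kruskal's algorithm
  with edges ordered by (descending weight, ascending `(i, j)`), so
  equal-weight ties resolve to the lexicographically smallest tree and
  reruns are bit-reproducible. Iteration stops when no edge-disjoint
  spanning tree remains or the round cap is hit; the GCE argmax is
  global rather than first-decline, which is robust to non-monotone GCE
  sequences.
* **Weighted vs binary.** The weighted graph is used only inside the GCE
  criterion (distance `1/w`); all reported efficiencies are computed on
  the binary OMST graph.
* **Disconnected subgraphs.** Local-efficiency subgraphs may be
  disconnected even though the OMST graph is connected; unreachable
  pairs contribute 0 (`1/Inf`), and nodes of degree < 2 get local
  efficiency 0 (the metric is undefined below two neighbors; 0 is the
  convention of the standard brain-connectivity toolboxes).
* **Standardization.** Continuous predictors, efficiency and (by
  default) the behavior are z-scored before fitting, and the interaction
  is the product of standardized age and efficiency, so `beta` is a
  standardized coefficient of magnitude comparable across behaviors.
  Raw-scale fitting is available.
* **FDR families.** For nodal and local efficiency, BH runs across the
  32 parcels within each (measure, metric, behavior); for global
  efficiency — one test per behavior — it runs across behaviors within a
  measure. The second family is a design choice (there is no canonical
  answer for a single-test metric) and is kept configurable.
* **LOO criterion.** Each fold's significance is judged on the
  uncorrected per-fold p-value at `loo_alpha`; folds whose design is
  rank-deficient are flagged and excluded from numerator and
  denominator. The pipeline computes reproducibility for FDR-significant
  tests by default (`loo = "significant"`), configurable to all tests or
  none.
* **Untestable columns.** A parcel whose efficiency is constant across
  subjects (common for local efficiency of low-degree nodes) cannot be
  standardized; the scan reports an NA row for it and applies FDR over
  the testable subset rather than aborting.

## The synthetic-cohort generator

`cohort_spec()` + `simulate_cohort()` generate complete studies so every
stage is testable without scan data. Defaults describe the study
conditions the package targets: 65 subjects aged 18–64 (balanced sex,
education ~ N(15.4, 3.2²) years), the 32-parcel parcellation with its
published vertex counts, and 30 histogram bins. Intracranial volume is
drawn from N(1.45 x 10^6, (1.5 x 10^5)²) mm³, a typical adult range.
Vertex values are log-normal for volume (location log 22 mm³) and area
(location log 9 mm²) — right-skewed and positive, matching per-vertex
scales of a 10k-vertex-per-hemisphere surface — and zero-truncated
normal around 2.5 mm for thickness. Homologous left/right parcels share
a distribution template (with shared subject-level jitter), so planted
pairs have reliably high similarity, emulating the strong homotopic
similarity of real cortices.

Behavior scores come from the interaction model's own forward equation,
with efficiency taken from the *real* pipeline run on the synthetic
morphometry — integration bugs therefore surface in parameter-recovery
tests. Default coefficients plant a negative age x efficiency
interaction of −0.3 in a "cognitive" score and +0.3 in an "emotional"
score, with noise SD 0.6 (signal-to-total variance near one half).

What the generator does **not** emulate: cortical geometry and spatial
autocorrelation along the surface, scanner/segmentation noise,
hemispheric asymmetries, or realistic covariance between age and
morphometry (age and vertex values are independent in the generator).
Passing recovery tests therefore demonstrate the pipeline's correctness
and statistical calibration, not that real cortices satisfy the
generative assumptions.

## Problem sizes used in validation

The test suite checks efficiency metrics exhaustively against
Floyd–Warshall and induced-subgraph oracles on *all* labeled connected
graphs up to 6 nodes plus 500 random graphs up to 8 nodes; OMST against
an exhaustive spanning-tree/GCE oracle on 100 random graphs up to 6
nodes; similarity properties on 200 random parcel pairs; GLM calibration
on 1000 null cohorts of n = 65 and recovery on 200 planted cohorts; and
end-to-end reproducibility on the full 65-subject, 32-parcel synthetic
study run twice from one seed.

## Known limitations

* The OMST literature contains several variant selection criteria; this
  implementation fixes one (edge-disjoint maximum spanning trees,
  global GCE argmax, `1/w` distances) and exposes per-round diagnostics
  so alternatives can be compared downstream without changing the
  filtering contract.
* FreeSurfer surface formats are not read directly; the package consumes
  a plain vertex-table TSV, and upstream extraction must decide, e.g.,
  how per-vertex volume is defined.
* Group-level structural covariance networks and multi-feature
  (10-property) similarity networks are distinct methods and out of
  scope.
* With 30 bins, similarity estimates from very small parcels are noisy;
  the 50-vertex filter is the only guard. Bin-count sensitivity can be
  explored via `n_bins`, which is recorded in all outputs.
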