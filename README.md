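# morphnet

Single-subject **morphological similarity networks** of the human
cortex, with threshold-free OMST filtering, binary-graph efficiency, and
an age x efficiency interaction analysis of behavior.

Group-level structural covariance yields one network per cohort and
hides individual differences; tractography needs diffusion data. This
package implements a per-subject alternative for plain structural MRI:
two cortical parcels are connected to the extent that their
*distributions* of vertex-wise morphometry (cortical volume mm³,
surface area mm², thickness mm) look alike. It is aimed at researchers
relating individual brain organization to behavior — e.g. cognitive and
emotional test scores across the adult age range.

## Method

For each subject, measure, and pair of parcels *(i, j)*:

1. pool both parcels' vertex values and split the pooled range into 30
   equal-width bins (a shared axis);
2. count each parcel's vertex frequencies per bin;
3. the connection is Pearson's *r* between the two frequency vectors.

Parcels with < 50 vertices are excluded (32 parcels of a 51-region
functional parcellation survive). Connection magnitudes |r| are filtered
with **orthogonal minimal spanning trees** (OMST): round *m* adds the
maximum spanning tree edge-disjoint from previous rounds, and the union
kept is the round maximizing global-cost-efficiency
GCE(m) = GE_w − Cost(m). On the binarized graph, with L_ij the shortest
path length and 1/∞ := 0,

    E_glob(G)  = 1/(N(N−1)) · Σ_{i≠j} 1/L_ij
    E_nodal(i) = 1/(N−1)   · Σ_{j≠i} 1/L_ij
    E_local(i) = E_glob(G_i),  G_i = subgraph induced on i's neighbors

Behavior is then modeled by OLS on standardized variables,

    beh = α1·age + α2·E + α3·sex + α4·edu + α5·ICV + α6·morph + β·(age×E) + γ + ε

where `morph` is total volume / total area / mean thickness matched to
the network measure. β tests whether the efficiency–behavior association
changes with age; Benjamini–Hochberg FDR (q < 0.05) runs across the 32
parcels per family, and leave-one-out reproducibility is the percentage
of single-subject-deleted refits in which β stays significant.

## Worked example

A fully synthetic 65-subject study (no scan data needed): vertex-wise
morphometry is simulated per parcel, the real pipeline computes each
subject's network efficiency, and behavior is generated from the
interaction model with a planted β = −0.3 for the "cognitive" score.

```r
library(morphnet)
spec <- cohort_spec(seed = 1)          # 65 subjects, 32 parcels, ages 18-64
study <- simulate_cohort(spec, measure = "area")

sm <- filter_parcels(simulate_subject_morphometry(spec, 1))
build_similarity_matrix(sm, "area")
#> Similarity matrix: subject 'sub-001', measure 'area', 32 parcels, 30 bins
#>   off-diagonal range [0.285, 0.989], mean 0.809; degenerate pairs: 0

omst_select(absolutize(build_similarity_matrix(sm, "area")))
#> OMST filtering: 9 round(s) completed, m* = 2
#>   selected 62 edges on 32 nodes (cost 0.146, GCE 0.2915)

fit <- interaction_glm(study$cohort, "cognitive", "e_glob")
fit
#> Age x efficiency interaction model (cognitive ~ e_glob), n = 65
#>   interaction beta = -0.4286, t = -5.224, p = 2.575e-06

loo_reproducibility(study$cohort, "cognitive", "e_glob")
#> Leave-one-out reproducibility: 100.00% (65 folds, 65 used, alpha = 0.05)
```

The fitted β is negative (the planted −0.3 on the standardized-behavior
scale, within sampling error at n = 65), its p-value survives the
planted effect size, and the interaction is reproduced in all 65
leave-one-out folds. `run_pipeline()` executes the same chain from TSV
inputs and writes per-subject matrices, adjacencies, efficiency tables,
the stats table and an MD5 manifest; `inst/cli/morphnet.R` is a thin
command-line wrapper (`run`, `simulate` subcommands).

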