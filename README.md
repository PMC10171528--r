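# connpred

Predictive modelling of cognition from brain connectomes: does summarising
a connectivity matrix through graph-theory measures help a regression model
predict cognitive scores, compared with feeding it the raw connectivity
weights?

`connpred` implements the complete analysis needed to ask that question on
weighted, undirected structural (SC) and functional (FC) connectomes:

- **Connectome construction.** Structural weights from probabilistic
  tractography streamline counts,
  `W_ij = (M_ij + M_ji) / ((N_i + N_j) * s)`, where `M_ij` counts
  streamlines seeded in region *i* reaching region *j*, `N_i` is the number
  of seed voxels and `s` the streamlines initiated per voxel — so
  `W_ij = 1` exactly when every streamline arrives. Functional weights as
  `|tanh(z_ij)|` from Fisher-z correlation matrices. Proportional
  thresholding retains the strongest fraction of edges.
- **A 20-measure graph battery.** Nine node measures (degree,
  within-module degree z, strength, Onnela clustering, eigenvector
  centrality, betweenness, participation coefficient, eccentricity, local
  efficiency), three edge measures (edge betweenness, matching index, path
  transitivity) and eight global measures (average clustering,
  characteristic path length, small-world propensity, global efficiency,
  assortativity, modularity Q, transitivity, core size), all on the
  inverse-weight shortest-path structure computed by Floyd–Warshall.
- **SWR-PCR.** Principal component regression with embedded stepwise
  selection: predictors are orthogonalised by PCA, component scores enter a
  bidirectional stepwise search under `BIC = n ln(RSS/n) + k ln(n)` with a
  strict-improvement rule, and the selected coefficients are projected back
  to feature space.
- **Validation.** Bootstrap bias-corrected cross-validation (BBC-CV) of
  out-of-sample R², permutation tests of predictive performance (add-one
  corrected p), Wilcoxon rank-sum contrasts between bootstrap performance
  distributions, and BIC differences graded on Kass–Raftery evidence bands
  (weak 1–3, positive 3–20, strong 20–150).
- **A synthetic cohort generator** producing paired SC/FC matrices and
  cognitive scores with a *plantable* linear signal of known strength on
  any feature family, so every stage of the pipeline is testable with a
  recoverable ground truth and no data download.

The package is aimed at methodologists in network neuroscience who want a
tested, reproducible reference implementation of this model-comparison
pipeline, and at anyone who needs weighted graph metrics with explicit,
oracle-tested conventions.

## Worked example

Generate a 200-subject cohort on a 12-region parcellation with a linear
signal explaining 40% of score variance planted on raw structural
connectivity, then ask whether global graph measures predict as well as the
raw weights:

```r
library(connpred)

config <- cohort_config(n_subjects = 200, n_regions = 12,
                        samples_per_voxel = 500, voxels_per_region = c(20, 60),
                        sc_density = 0.6,
                        planted_r2 = 0.4, planted_feature_set = "raw_sc",
                        n_signal_features = 5, seed = 11)
cohort <- generate_cohort(config)
cohort
#> Synthetic connectome cohort: 200 subjects, 12 regions
#>   planted R2 0.40 on 'raw_sc' features

conns <- prepare_connectomes(cohort, "SC", retain_fraction = 0.2)
conns[[1]]
#> <connectome> SC, 12 regions, 9 edges (thresholded)

round(compute_subject_metrics(conns[[1]], seed = 1)$global, 3)
#> average_clustering_coefficient     characteristic_path_length
#>                          0.000                         62.473
#>         small_world_propensity              global_efficiency
#>                          1.000                          0.017
#>                  assortativity           modularity_statistic
#>                         -0.123                          0.498
#>                   transitivity                      core_size
#>                          0.000                          4.000

res <- run_study(cohort, sets = "global", modalities = "SC",
                 domain = "Executive Function", folds = 10, B = 1000,
                 n_perm = 1000, seed = 7)
res$models[["SC"]][["raw"]][["Executive Function"]]$cv
#> <cv_result> corrected R^2 = 0.223 (apparent 0.384, pooled 0.231), permutation p = 0.000999
res$comparisons[["SC"]][["global"]][["Executive Function"]]
#> <model_comparison> dBIC = -55.40 (strong evidence for M1); Wilcoxon Z = 32.03, p = 4.44e-225
```

Reading the output: the raw-connectivity model — the family the signal was
planted on — recovers about half of the planted variance out of sample
(bias-corrected R² 0.22 against a generative ceiling of 0.4; the drop is
the cost of learning 5 signal columns among 66 under cross-validation) and
beats chance (p ≈ 0.001). The in-sample BIC difference of −55 is strong
evidence for the raw model over the global-metric model (M1 = raw by the
first-argument convention), and the Wilcoxon Z of +32 says the raw model's
bootstrap R² distribution dominates. Exactly the right answer for this
cohort: compressing the matrix to eight global summaries discards the
planted information.

Cohorts round-trip through plain-text files (`write_cohort()` /
`read_cohort()`), and a thin command-line wrapper with `simulate` and
`evaluate` subcommands lives in `inst/cli/connpred.R`.

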