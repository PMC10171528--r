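---
title: "Methods: graph-theoretic versus raw-connectivity prediction of cognition"
author: "connpred"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graph-theoretic versus raw-connectivity prediction of cognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connpred)
```

## The question and the design

Given per-subject weighted connectomes — structural (SC, from
streamline-count tractography) and functional (FC, from resting-state
correlations) — and per-subject cognitive domain scores, we compare two
families of predictive models: one fed the raw connectivity weights, one
fed graph-theory summaries of the same matrices (node-, edge- or
global-level, alone or stacked). Both families use the same learner
(SWR-PCR, below) and the same validation machinery, so any performance gap
is attributable to the featurisation, not the fitting procedure.

Real cohorts of this kind are access-controlled, so the package ships a
synthetic cohort generator whose output obeys exactly the structural
invariants the pipeline expects and whose cognitive scores contain a linear
signal of *known* location and strength. Every claim the test suite makes
is therefore checked against a recoverable ground truth.

## The synthetic cohort generator

**Structural counts.** Each subject's matrix `M` holds streamline counts:
`M[i, j] ~ Binomial(N[i] * s, p[i, j])`, where `N[i]` is region *i*'s
seed-voxel count (uniform over a configurable range), `s` the streamlines
initiated per voxel (default 5000, matching standard probabilistic
tractography practice; reduced in tests for speed) and `p[i, j]` a
subject-level connection probability. Probabilities are a cohort template —
log-normal across edges (`meanlog = log(0.02)`, `sdlog = 1`), because
tract-density weights are heavy-tailed and small — times a per-subject
log-normal deviation with scale `sc_deviation_sd`. The template/deviation
split matters: between-subject variance is what the downstream regression
consumes, so it is an explicit dial rather than an emergent accident.
Counts are asymmetric (`M[i, j] != M[j, i]`) but correlated across
directions, as in real tractography, because both are draws from the same
`p[i, j]`.

**Functional matrices.** Correlations arise from a latent-factor model:
region *i* carries a loading row `u_i` (norm < 1) on `fc_latent_dim`
shared factors, and the population correlation is `R = U U'` off the
diagonal. This guarantees a valid (positive semidefinite) correlation
structure with genuinely correlated features — important because the
behaviour of PCA, cross-validation and permutation tests depends on feature
correlation, which element-wise noise would not reproduce. Subject
deviations perturb the loadings; measurement noise (`fc_noise_sd`) is added
on the Fisher-z scale, which is where such matrices are reported.

**Planted signal.** Cognitive scores are `y = X beta + eps` with `X` the
*configured feature family computed by the downstream modules themselves*
(raw SC/FC weights, or node/edge/global metrics of the thresholded SC
graph). Planting after thresholding and metric computation closes the loop:
the ground truth refers to quantities the pipeline actually sees, not to
latent constructs it cannot recover. `beta` is standard normal on
`n_signal_features` standardised columns and the noise scale is set so that
`var(X beta) / var(y)` equals `planted_r2` in expectation; the realised
sample ratio fluctuates around it (at n = 2000 it converges to within
±0.05, which the test suite exercises at reduced scale). Defaults —
249 subjects, 278 regions — mirror the cohort scale the pipeline is
designed for; tests and the acceptance script use 10–20 regions and
60–200 subjects, chosen so the full suite runs in about a minute while
keeping every estimator in a sane regime.

What the generator does **not** emulate: voxel-level MRI physics, head
motion, scanner artefacts, or the empirical distribution of real
streamline counts. Passing tests show the pipeline is correct and honest
under known ground truth — not that any particular empirical effect size
will replicate.

## Connectome preparation

SC weights are `W_ij = (M_ij + M_ji) / ((N_i + N_j) s)`: the observed
two-way streamline count over its maximum, symmetric by construction and
saturating at 1 when every initiated streamline arrives. FC weights are
`|tanh(z)|`: the inverse Fisher transform recovers correlations in (−1, 1)
and the absolute value keeps the magnitude of negative couplings, applied
*before* thresholding.

"An 80% proportional threshold" is read here as *discard the weakest 80%*
(`retain_fraction = 0.2`), consistent with the moderate-to-high
thresholding this convention is meant to achieve; the opposite reading is
one argument away. Two further conventions: for sparse SC matrices only
nonzero entries count toward the quota (an absent tract is not a "weak
edge"), while for dense FC matrices every off-diagonal pair is a
candidate; and ties at the cut are broken by (weight descending, row,
column), so surviving edge sets are deterministic and nested across
fractions.

## The graph battery and its conventions

All path-based quantities use edge lengths `1/w` (strong connections are
short) and the Floyd–Warshall algorithm, extended with exact
shortest-path multiplicity counts and a successor matrix. Equal-length
alternatives are detected at relative tolerance 1e-10, because two
floating-point routes of equal true length can differ in their last bits.

Where a measure has several definitions in circulation, the package pins
one and tests it against an independent brute-force oracle (min-plus
closure for distances, explicit path enumeration for betweenness,
definitional loops for the rest) on random connected graphs:

- **Clustering (node and global):** Onnela's form — geometric mean of
  triangle weights normalised by the maximum weight; transitivity is the
  corresponding ratio form (total triangle intensity over total triads).
- **Betweenness (node and edge):** raw counts of shortest paths through a
  node (endpoints excluded) or edge (endpoints included), with equal-length
  multiplicities counted exactly rather than split fractionally.
- **Matching index:** weighted neighbourhood overlap — the sum of
  `W[i,k] + W[j,k]` over common neighbours divided by the same sum over the
  union of neighbourhoods (which reduces to `s_i + s_j − 2 W[i,j]`),
  excluding the mutual edge; 1 for identical neighbourhoods, 0 for
  disjoint ones.
- **Path transitivity:** the mean matching index over all pairs of nodes
  on the reconstructed shortest path, endpoints included; the literature
  leaves the normalisation open, and this density-over-the-path form keeps
  the value in [0, 1] and reduces to the matching index for adjacent
  pairs. Disconnected pairs score 0.
- **Participation / within-module degree:** participation uses strengths
  (`1 − Σ_m (κ_im/s_i)²`); within-module degree is the z-scored binary
  degree within the node's own module — the standard companion definition.
- **Modules:** Newman's leading-eigenvector bipartitioning on the
  modularity matrix, recursing with the generalised modularity matrix and
  a deterministic single-flip refinement. The procedure is deterministic;
  the seed argument exists for interface symmetry and is recorded.
- **Eigenvector centrality:** computed on the largest connected component
  (elsewhere the leading eigenvector is not unique), nonnegative, unit
  norm, zeros off-component.
- **Assortativity:** Pearson correlation of endpoint strengths across
  edges; `NaN` sentinel when strengths have zero variance (regular
  graphs), imputed downstream.
- **Small-world propensity:** `φ = 1 − sqrt((ΔC² + ΔL²)/2)`, with the
  clustering deviation measured against a weighted ring-lattice null
  (strongest weights at smallest circular distances) and the path-length
  deviation against a weight- and density-preserving random null, each
  ratio clamped to [0, 1] and averaged over 10 seeded null instances; a
  vanishing null spread maps to deviation 0 or 1 by the sign of the
  numerator. A ring lattice itself scores ≈ 1 − sqrt(1/2) ≈ 0.29, which
  the tests check.
- **Core–periphery size:** the core of the two-block partition maximising
  the centred coverage quality `Σ_{i<j, i or j ∈ core} (W_ij − w̄)`
  (`w̄` = mean off-diagonal weight). Centring penalises sweeping weak
  pairs into the core, so a hub-and-spoke graph yields a one-node core
  while a uniform complete graph ties every assignment and the
  larger-core tie-break returns the full set. Search is exhaustive up to
  12 nodes and strength-ordered sweep plus single-toggle hill climbing
  beyond.

Disconnection handling: thresholding to 20% density can fragment a graph,
so characteristic path length and eccentricity are computed over finite
distances only (with a warning), infinite pairs contribute 0 to global
efficiency, and isolated nodes get eccentricity `NA` — imputed later with
training-fold means so the regression never sees undefined values. The
battery deliberately counts 20 measures (9 + 3 + 8).

## SWR-PCR

Features are standardised (mean 0, sd 1) by default — the measures live on
wildly different scales, and PCA on unstandardised columns would be
dominated by whichever measure has the largest units; it can be switched
off. PCA retains every rank-supported component (no variance cutoff: the
stepwise search, not a hard threshold, decides what carries signal). The
stepwise search starts from the intercept-only model and at each step
evaluates every single addition and removal, applying the move with the
largest *strict* BIC decrease — the zero-threshold reading of "ΔBIC = 0" —
with ties broken toward the smaller model, then the lower component index.
Bidirectional search is the default and forward-only a config option;
on exactly orthogonal scores the two coincide (each component's RSS
contribution is separable), which the implementation exploits for speed,
falling back to explicit least squares for non-orthogonal inputs.

BIC uses the Gaussian profile-likelihood form
`n ln(RSS/n) + k ln(n)` with `k` counting intercept and slopes; the error
variance is profiled out identically in all compared models, so only
differences matter — which is all the pipeline ever uses. A numerically
zero RSS returns a large negative sentinel with a warning rather than
−Inf.

Selected coefficients are back-projected to feature space through the
loading matrix; predictions from the component-space and feature-space
parameterisations agree to 1e-10, which is asserted on random models.

## Validation

**BBC-CV.** K-fold cross-validation (default K = 10, folds stratified by
outcome quantile, seeded) with *all* preprocessing — imputation,
standardisation, PCA, stepwise selection — re-estimated inside each
training fold; held-out subjects are transformed with training-fold
parameters only. Out-of-fold predictions are pooled, then B = 1000
bootstrap resamples of subject indices are drawn and R² is evaluated on
each resample's out-of-bag complement from the pooled predictions; the
corrected estimate is the mean of that distribution. This is the
bias-corrected *performance estimation* use of the bootstrap (one
configuration per feature family); the companion configuration-selection
machinery is out of scope here. The apparent R² reported alongside is the
in-sample fit of the model trained on all subjects, so the
corrected-versus-apparent gap displays optimism directly.

**Permutation test.** The pairing of pooled predictions with outcomes is
shuffled (sampling without replacement; 10,000 times at full scale, 1000
in tests) and R² recomputed; permutations at least as high as the observed
value count as exceedances, including exact ties. The add-one correction
`p = (1 + #exceed)/(1 + n_perm)` is the default so p is never exactly
zero; the plain proportion is available by flag.

**Wilcoxon rank-sum.** Midranks for ties, tie-corrected variance,
continuity correction, and the first-argument sign convention (`Z > 0`
means the first model's distribution is larger). For tie-free pooled
samples of at most 50 values the exact rank-sum distribution is used by
default — at such sizes the normal approximation is off by far more than
any sensible tolerance (one-sided exact 1/6 versus normal 0.12 at
2 + 2) — while the bootstrap-distribution contrasts (2000 values) always
take the normal path.

**Model comparison.** `ΔBIC = BIC(M1) − BIC(M2)`, graded |ΔBIC| < 1
negligible, 1–3 weak, 3–20 positive, 20–150 strong, > 150 very strong,
signed toward the favoured model. Following the design this package
mirrors, performance contrasts are only run when both models beat chance
(permutation p < 0.05); the BIC grading is reported regardless. No
multiple-comparison correction is applied across the
domains × families × modalities grid, matching the comparative (not
confirmatory) intent.

## Numerical choices, degenerate inputs, limitations

Symmetry and identity checks use 1e-12 relative tolerance; shortest-path
ties 1e-10; PCA rank truncation 1e-8 on singular values. Edgeless graphs
are rejected by the partition, propensity and core–periphery routines with
explicit errors; zero-variance feature columns error at standardisation
unless explicitly tolerated (as inside cross-validation, where a
training-fold-constant column becomes identically zero and is ignored by
PCA).

Known limitations: stepwise-BIC over many near-orthogonal candidates is
selection-biased when the candidate count approaches the sample size — the
greedy maximum of hundreds of score gains easily clears the `ln(n)`
penalty — so high-dimensional families can overfit in-sample; BBC-CV
exposes this honestly (corrected R² collapses while apparent R² soars),
which is precisely the argument for validating every family identically.
Edge-level features are aligned across subjects on the union of surviving
edges with zero fill, a pragmatic answer to subject-varying edge sets.
The generator's realism claims are structural, not distributional; results
on synthetic cohorts demonstrate correctness and calibration of the
machinery, and transfer to real cohorts only to the extent their signal
really is linear in the chosen features.
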