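---
title: "Multiscale functional network features: models, choices and caveats"
author: "netscale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale functional network features: models, choices and caveats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netscale)
```

# What the package computes

`netscale` studies how the *node scale* of a functional brain-network
parcellation affects machine-learning classification of a two-group
resting-state fMRI cohort. The pipeline is:

1. **Parcellation.** A parent atlas (for real data, a ~90-region anatomical
   template) is refined into approximately `N` nodes by volume-proportional
   seeded region growing (`subdivideAtlas()`).
2. **Networks.** Per subject, node-mean time series are extracted, nuisance
   regressors are removed by least squares, a Pearson correlation matrix is
   formed, and the matrix is binarized at each sparsity `S` in a grid
   (`buildFeatureTable()` runs all of this).
3. **Features.** At each `S`, three nodal metrics are computed — degree,
   betweenness centrality, nodal efficiency — and each metric's curve over
   the grid is collapsed to one value per node by trapezoidal integration,
   giving `3 * N` features per subject.
4. **Screening.** Each feature is tested patients-vs-controls with a
   two-sample Kolmogorov–Smirnov test; Benjamini–Hochberg FDR control at
   `q = 0.05` defines the discriminative set (`screenFeatures()`).
5. **Classification.** A linear SVM under repeated stratified 10-fold
   cross-validation produces accuracy / sensitivity / specificity
   (`repeatedKFold()`); `accuracyVsFeatureCount()` sweeps the number of
   P-ranked features; `nestedHoldoutProtocol()` runs a 70/30 split with an
   inner C-grid search.
6. **Feature evaluation.** Features are discretized to three states and
   scored with minimum-redundancy–maximum-relevance mutual-information
   quantities: relevance `D = (1/|S|) Σ I(h, i)`, redundancy
   `R = (1/|S|²) Σ I(i, j)` and their difference `MID = D − R`
   (`table2Scores()`, `perFeatureMid()`), plus a regression of pairwise
   redundancy on inter-node centroid distance
   (`redundancyDistanceRegression()`).

No clinical data ship with the package; a synthetic cohort generator with
*planted* group effects (`generateAtlas()`, `generateCohort()`) makes every
stage testable end to end.

# The synthetic data model

Each parent region `r` receives a latent signal `l_r(t)`: a unit-variance
AR(1) series (coefficient `arCoef = 0.3`, mimicking BOLD autocorrelation at
TR ≈ 2 s) whose innovations are spatially correlated across regions with
`Cor(l_r, l_s) = exp(−d_rs / spatialDecayMm)` (default length scale 20 mm).
The spatial decay serves two purposes: it is the distance-dependent signal
sharing that makes nearby nodes genuinely similar — the substrate of the
redundancy-vs-distance analysis — and it is a realistic feature of smoothed
BOLD data. A voxel in region `r` observes `l_r(t)` plus iid Gaussian noise
(`noiseSd = 1`) plus a region-weighted mixture of eight nuisance regressors
(six slow motion-like sinusoids with jitter, two AR(1) tissue-like signals;
weights per region with SD `nuisanceAmplitude = 0.5`). The regressors are
recorded per subject so `nuisanceRegress()` can remove them exactly at the
node level. Bandpass filtering is not re-implemented: the latents are
already band-limited by construction.

**The planted effect.** In patients only, a shared hub AR(1) signal is mixed
into the latents of the `effectRegions`:
`l ← sqrt(1 − e) · l + sqrt(e) · hub`, with `e = effectSize`. Two affected
regions with baseline correlation ρ then correlate at `(1 − e) ρ + e`, so
their nodal degree and efficiency rise as a group difference — the premise
of the screening stage.

**The effect is focal.** Only the fraction `effectFraction` (default 0.5) of
each affected region's voxels — the compact subvolume nearest the region
centroid — carries the mixture. This is a deliberate design decision. If an
effect is uniform over a parent region, the coarsest parcellation is
provably the best: averaging all of a homogeneous region's voxels is the
ideal denoiser, and subdividing can only add noise. Under such a generator,
finer parcellations would *never* help, and the scale phenomenon the
package exists to study would be unrepresentable. A sub-region effect scale
is exactly what finer nodes resolve: a coarse node dilutes the affected
subvolume with unaffected voxels, while a fine node can isolate it. With
`effectFraction = 1` the effect is region-uniform (useful for testing
mechanics of the screening stage in isolation).

The generator does **not** model hemodynamic forward dynamics, scanner
noise physics, spatial smoothing kernels, or subject-level anatomy
differences. Consequently, passing tests demonstrate internal correctness
and qualitative replications of scale effects on this model — not claims
about any clinical population.

What neither the literature nor desk reasoning pins down is the *magnitude*
of real group effects; `effectSize` is a free simulation parameter. The
package uses 0.4 for planted-effect studies: large enough that a cohort of
a few dozen subjects has nontrivial power, small enough that accuracies
stay well below ceiling at coarse scales.

# Parcellation algorithm and its ambiguities

Subregion counts are `k = round(V · N)` per parent, where `V` is the
parent's share of foreground voxels. Rounding is half-up, floored at 1, so
every parent survives and the parent map stays surjective; the achieved
total can deviate from `N` by up to half the parent count (this bound is
tested). Growth then proceeds per parent independently — subregions never
cross parent boundaries:

* `k` seed voxels are drawn uniformly without replacement, from an RNG
  stream namespaced by region id, so results do not depend on the order in
  which regions are processed.
* Repeatedly, the globally nearest (unassigned voxel, seed) pair — by
  Euclidean distance in mm, using the voxel spacing — is merged, and that
  seed moves to the running mean of all voxel centres merged into it.
* Ties are broken by (voxel linear index, seed index).

The published description of this family of algorithms is ambiguous about
whether voxels are claimed in sweeps or one at a time and where a seed sits
after its first merge. The global priority-queue reading used here makes
the result independent of voxel enumeration order and keeps every step
well-defined; the running-mean re-centring generalises "the physical centre
of the merged pair" beyond the first merge. Both choices are deterministic
given the seed and are frozen in tests. Centroids are arithmetic mass
centres in mm.

# Network construction choices

* **Edges** are Pearson correlations of nuisance-regressed node means.
  Operationally this is correlation-of-residuals; a true inverse-covariance
  partial correlation is out of scope (and ill-posed at node counts above
  the subject's time-series length).
* **Proportional thresholding**: sparsity `S` keeps the
  `round(S · n(n−1)/2)` strongest upper-triangle entries. The default
  ranking is *signed* (most-positive first), matching common practice for
  binary functional networks; `ranking = "absolute"` is available because
  the alternative reading is defensible. Ties are broken lexicographically
  by (i, j), which matters on synthetic data with exact ties.
* **Grid**: `{0.08, 0.13, 0.18, 0.23, 0.28}` — a 5% step through the
  (8%, 32%) window. The exact endpoint inside that open interval is not
  recoverable from the usual prose description; the grid is configurable.
* **No global signal regression** — only the recorded nuisance regressors
  are removed.

An important side effect of proportional thresholding, visible in the
synthetic replications: because the edge budget is fixed, a planted
connectivity *increase* among affected nodes necessarily *removes* edges
elsewhere, so unaffected nodes also acquire group differences of opposite
sign. Screening therefore flags more than the anatomically affected
regions; tests assert recovery of the planted regions among the strongest
signals rather than exclusivity.

# Metrics

Degree is a row sum. Betweenness is normalized by `(n−1)(n−2)/2` so values
are comparable across scales; unnormalized values are available since
formula sheets in this literature sometimes omit the normalisation. Nodal
efficiency is the mean inverse shortest-path distance with `1/∞ = 0`;
unreachable pairs likewise contribute nothing to betweenness. Both are
needed because low-sparsity, high-N graphs fragment. The AUC is a plain
trapezoid on the raw grid, with no renormalisation by the grid range —
values across different grids are therefore not directly comparable, by
design. Shortest-path machinery is delegated to igraph; the test suite
validates both metrics against an independent brute-force oracle built
from adjacency-matrix powers on hundreds of random graphs.

# Screening

KS P values are asymptotic by default (`exact = TRUE` available). Two
caveats are deliberate and documented rather than patched:

* The KS statistic is discrete, so its P values are *conservative* at
  case-control sizes of a few dozen per group: the uncorrected null
  rejection rate at 0.05 sits near 0.02–0.04, not 0.05. Tests assert the
  one-sided property (rate ≤ nominal + 3 SE) — which is what FDR control
  inherits — because a two-sided calibration band around 0.05 is
  unattainable for any two-sample KS test at these sizes.
* The BH family is all features of a parcellation pooled (one family per
  scale). Correcting within each metric separately is supported
  (`family = "per_metric"`); which the field's typical description intends
  is genuinely ambiguous, so the choice is a flag, not a guess.

# Classification

The SVM is LIBSVM's linear kernel via e1071, stopping tolerance `1e-3`,
default `C = 1`. Folds are stratified by group (at ~66 subjects,
unstratified 10-fold draws produce single-class test folds often enough to
matter); unstratified mode exists. Standardization uses training-fold
statistics only — the anti-leakage canary (shuffled labels must classify at
chance) guards this. Screening, however, happens *once on the full sample*
before cross-validation, mirroring the screen-then-validate order this
study design describes; the optimistic bias that induces is real and known.
The honest alternative — re-screening inside every training fold — is
available by passing any feature subset you like to `repeatedKFold()`
per fold-wise pipeline you construct; the shipped orchestration reports the
literature-style number.

The hold-out protocol's C grid is `2^c, c ∈ −5…5`: a "range [−5, 5] in
steps of 1" cannot mean raw (nonpositive) costs, and the log2 grid is the
standard reading. Ties in inner-CV accuracy resolve to the smallest C.

One qualitative claim from this literature does **not** replicate under the
iid generator and is not asserted on synthetic data: a *positive*
regression of held-out test accuracy on inner validation accuracy across
random 70/30 splits. With a fixed finite cohort, every informative or
difficult subject lands in exactly one of the two sets, which induces
negative dependence between the two accuracies; in simulation this
resampling effect dominates model-quality coupling at every effect size,
dimension and sample size tried (slopes were consistently negative even at
38/28 subjects and 100 repeats, while the *magnitudes* of the adjusted R²
matched the range reported in comparable studies). The protocol itself is
implemented faithfully and its regression output is tested against an
independent refit; interpreting the sign on real, heterogeneous cohorts is
left to the analyst.

# mRMR evaluation

Features are discretized to three states at `mean ± α·SD` with `α = 1`
(the common binning for this method; configurable). Mutual information is
the plug-in estimate in bits. Two per-feature "effectiveness" readings are
implemented because the underlying definition is under-specified:

* the **incremental** mRMR score — each feature keeps the score
  `I(h, i) − mean_j I(i, j)` it had at its own greedy selection step
  (`perFeatureMid()`); this is what mRMR toolkits emit;
* the **literal set formula** applied to singletons,
  `MID = I(h, i) − H(i)` (`table2Scores()` with one feature).

The set-level `R` includes the `i = j` self-information terms exactly as
the set formula is written; the pairwise redundancy *report*
(`redundancyMatrix()`) excludes self-pairs. Both behaviours are unit-tested.
For the effectiveness-vs-P regression the incremental score is used, with a
caveat found in simulation: in strong-signal regimes the greedy redundancy
penalty hits precisely the low-P features that are selected late, which
flattens the per-dataset regression; the direction (negative slope) is
asserted per seed, and significance on data pooled across seeds and scales,
where it is extremely strong.

Distances for redundancy-vs-distance pairs are centroid distances of the
two features' nodes; pairs of features on the same node (different metrics,
distance 0) are excluded as degenerate.

# Problem sizes and reproducibility

All randomness flows from explicit integer seeds: the atlas, each subject's
series (per-subject namespaced substreams), each region's growing seeds
(per-region substreams), every fold draw. Two calls with the same seed are
bitwise identical; this is tested.

The test suite and the acceptance script run on purpose-built small
problems: a 14×14×10 ellipsoidal atlas (~1000 foreground voxels, 6
parents), cohorts of 38/28 subjects with 120 timepoints for planted-effect
studies (8/8 × 40 for null calibration), scales N ∈ {6, 24}, 5–50 CV
repeats depending on the stage. These sizes were chosen so that effects are
detectable but not saturated and the full suite completes in minutes; the
pipeline itself has no size assumptions beyond memory.

# Known limitations

* Binary graphs only; no weighted metrics, no global metrics, no community
  structure.
* The generator's focal-effect geometry (a ball around the region centroid)
  is one of many plausible choices; effect placement at region boundaries
  would stress parcellation alignment differently.
* MI estimates at three states and n ≈ 66 carry a positive bias of order
  0.04 bits; comparisons are within-dataset, where the bias largely
  cancels, but absolute MID values should not be over-interpreted.
* `subdivideRegion()` is quadratic in region voxel count and intended for
  desk-scale atlases; a production run on a full-resolution brain would
  want a spatial index.
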