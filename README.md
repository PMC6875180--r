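# netscale

Multiscale functional brain-network construction, feature screening and
classification in R.

## The problem

When resting-state fMRI is turned into a functional connectivity network,
someone has to decide how many nodes the brain gets. The choice of
parcellation scale — 90 anatomical regions, or the same volume split into
hundreds or thousands of subregions — changes the network's topology, the
nodal features extracted from it, and ultimately the accuracy of any
classifier built on those features. `netscale` implements the full analysis
pipeline needed to study this question quantitatively, for methodologists
working on network neuroimaging and machine-learning pipelines on
case-control cohorts:

- **Parcellation at configurable scale.** A parent label atlas is refined
  into ≈ N nodes by volume-proportional seeded region growing: each parent
  region with volume fraction V gets k = round(V·N) subregions, grown from
  random seed voxels by repeatedly merging the globally nearest
  (voxel, seed) pair and re-centring the seed on its running mass centre.
  Subregions never cross parent boundaries.
- **Network features.** Per subject: node-mean time series → nuisance
  regression → Pearson correlation matrix → binarization at proportional
  sparsity thresholds S ∈ {0.08, 0.13, 0.18, 0.23, 0.28}. At each S, three
  nodal metrics are computed — degree kᵢ, betweenness centrality bᵢ
  (normalized by (n−1)(n−2)/2), nodal efficiency
  Eᵢ = (1/(n−1)) Σ_j 1/d(i,j) — and each metric's curve over S is collapsed
  by trapezoidal AUC into one feature, giving 3N features per subject.
- **Screening.** Two-sample Kolmogorov–Smirnov tests per feature with
  Benjamini–Hochberg FDR control (q = 0.05) define the discriminative set.
- **Classification.** Linear SVM under repeated stratified 10-fold
  cross-validation (accuracy, sensitivity, specificity, training accuracy),
  an accuracy-vs-feature-count sweep along the P-value ranking, and a
  nested 70/30 hold-out protocol with an inner search over C = 2^c,
  c ∈ −5…5.
- **Feature evaluation (mRMR).** On three-state discretized features:
  relevance D = (1/|S|) Σᵢ I(h, i), redundancy R = (1/|S|²) Σᵢⱼ I(i, j),
  and their difference MID = D − R, per feature and per subset, plus the
  regression of pairwise redundancy on inter-node centroid distance.

Because clinical imaging data cannot ship with a package, `netscale`
includes a synthetic rs-fMRI cohort generator (AR(1) region latents with
distance-decaying spatial correlation, focal hub-mixing effects planted in
chosen regions, recorded nuisance regressors) so that every stage — and
every claimed scale effect — is testable end to end. See the vignette
(`vignettes/multiscale-networks.Rmd`) for the data model and the design
decisions.

## Worked example

```r
library(netscale)

atlas  <- generateAtlas(c(14, 14, 10), nRegions = 6, seed = 1)
spec   <- cohortSpec(nPatients = 20, nControls = 20, nTimepoints = 120,
                     effectRegions = c(1, 2), effectSize = 0.4, seed = 7)
cohort <- generateCohort(atlas, spec)
parc   <- subdivideAtlas(atlas, N = 24, seed = 42)
parc
#> ParcellationScheme: target N = 24 | achieved N = 24
#>   parents: 6 | seed: 42

tab    <- buildFeatureTable(cohort, parc)   # 72 features x 40 subjects
screen <- screenFeatures(tab, q = 0.05)
sel    <- selectFeatures(screen, "fdr", 0.05)
cv     <- repeatedKFold(tab, features = sel, k = 10, repeats = 20, seed = 1)
cv
#> CVResult (10-fold x 20 repeats, 1 features)
#>   accuracy 0.834 | sensitivity 0.850 | specificity 0.818 | train 0.839
```

The atlas is a 14×14×10 grid whose ellipsoidal foreground (1072 voxels,
3 mm isotropic) is split into 6 parent regions; the cohort plants a focal
connectivity increase (hub-signal mixing, size 0.4) in regions 1–2 of the
patient group. At scale N = 24 the screen finds the discriminative AUC
features (here one survives FDR at this small sample; its raw
P ≈ 1.1 × 10⁻⁶), and the linear SVM classifies held-out subjects at ~83%
accuracy — well above the ~50% obtained when labels are shuffled, which is
the package's anti-leakage canary.

`runScaleSweep()` repeats all of this across several N and collects
per-scale feature counts, CV rates, the accuracy-vs-feature-count curve
and the mRMR analyses into one report; `sameFeatureCountComparison()`
re-fits classifiers with the number of features held fixed across scales.
Thin command-line wrappers for parcellation and the sweep live in
`inst/scripts/`.

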