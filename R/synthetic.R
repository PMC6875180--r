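# Synthetic atlas volumes and two-group voxel time-series cohorts with known
# planted connectivity effects, so every downstream stage is testable without
# any imaging download.

#' Generate a synthetic labelled atlas
#'
#' Partitions an ellipsoidal foreground mask (inscribed in the grid, so that
#' regions have unequal voxel volumes) into `nRegions` spatially compact
#' regions by nearest-seed Voronoi assignment of uniformly drawn seed voxels.
#' Output is deterministic given `seed`.
#'
#' @param shape integer length-3 grid dimensions.
#' @param nRegions number of parent regions to create.
#' @param spacing voxel size per axis in mm (default 3 mm isotropic).
#' @param seed RNG seed.
#' @return A [LabelAtlas-class] with regions labelled `1:nRegions`.
#' @examples
#' atlas <- generateAtlas(c(12, 12, 10), nRegions = 5, seed = 1)
#' atlas
#' @export
generateAtlas <- function(shape, nRegions, spacing = c(3, 3, 3), seed = 1) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L), nRegions >= 1L)
  ctr <- (shape + 1) / 2
  ax <- pmax(shape / 2, 0.5)
  g <- expand.grid(i = seq_len(shape[1L]), j = seq_len(shape[2L]),
                   k = seq_len(shape[3L]))
  inside <- ((g$i - ctr[1L]) / ax[1L])^2 + ((g$j - ctr[2L]) / ax[2L])^2 +
    ((g$k - ctr[3L]) / ax[3L])^2 <= 1
  fg <- which(inside)
  if (nRegions > length(fg))
    stop("nRegions (", nRegions, ") exceeds the ", length(fg),
         " foreground voxels")
  xyz <- voxel_coords_mm(fg, shape, spacing)
  seeds <- with_rng(seed, sample(length(fg), nRegions))
  # nearest seed in mm; ties resolved to the lowest seed index by which.min
  lab <- integer(length(fg))
  d2 <- matrix(0, length(fg), nRegions)
  for (s in seq_len(nRegions)) {
    d2[, s] <- (xyz[, 1L] - xyz[seeds[s], 1L])^2 +
      (xyz[, 2L] - xyz[seeds[s], 2L])^2 + (xyz[, 3L] - xyz[seeds[s], 3L])^2
  }
  lab <- max.col(-d2, ties.method = "first")
  labels <- array(0L, dim = shape)
  labels[fg] <- lab
  LabelAtlas(labels, spacing)
}

#' Specify a synthetic cohort
#'
#' Bundles and validates the simulation parameters for [generateCohort()].
#' Group sizes and series length default to a typical small clinical
#' rs-fMRI case-control study (38 patients, 28 controls, 238 retained
#' volumes at TR 2 s).  The planted effect defaults to none: pass
#' `effectRegions` and a positive `effectSize` to plant a group difference.
#'
#' @param nPatients,nControls subjects per group (each >= 2).
#' @param nTimepoints series length (>= 8).
#' @param effectRegions integer ids of parent regions whose connectivity is
#'   raised in the patient group.
#' @param effectSize dimensionless mixing weight in `[0, 1)`: the fraction of
#'   hub-signal variance mixed into affected regions' latents for patients.
#'   A pair of affected regions with baseline latent correlation rho attains
#'   correlation `(1 - effectSize) * rho + effectSize` within the affected
#'   subvolumes.
#' @param effectFraction fraction in `(0, 1]` of each affected region's
#'   voxels (the compact subvolume nearest the region centroid) that carry
#'   the effect.  Values below 1 emulate focal pathology: a coarse node
#'   averages affected with unaffected voxels and dilutes the signal, while
#'   finer parcellations can isolate the affected subvolume.
#' @param noiseSd per-voxel iid noise SD (signal units, > 0).
#' @param arCoef AR(1) coefficient of latent signals, mimicking BOLD
#'   autocorrelation.
#' @param spatialDecayMm length scale (mm) of the exponential decay of
#'   baseline latent correlation with inter-region centroid distance; this is
#'   the distance-dependent signal sharing that spatially close nodes inherit.
#' @param nuisanceAmplitude SD of the per-region weights with which the
#'   nuisance regressors are mixed into the signal.
#' @param seed RNG seed.
#' @return A validated list of class `CohortSpec`.
#' @export
cohortSpec <- function(nPatients = 38, nControls = 28, nTimepoints = 238,
                       effectRegions = integer(0), effectSize = 0,
                       effectFraction = 0.5, noiseSd = 1, arCoef = 0.3,
                       spatialDecayMm = 20, nuisanceAmplitude = 0.5,
                       seed = 1) {
  if (nPatients < 2 || nControls < 2)
    stop("each group needs at least 2 subjects")
  if (nTimepoints < 8)
    stop("nTimepoints must be >= 8")
  if (effectSize < 0 || effectSize >= 1)
    stop("effectSize must be in [0, 1)")
  if (effectFraction <= 0 || effectFraction > 1)
    stop("effectFraction must be in (0, 1]")
  if (!is.numeric(noiseSd) || noiseSd <= 0)
    stop("noiseSd must be positive")
  structure(list(
    nPatients = as.integer(nPatients), nControls = as.integer(nControls),
    nTimepoints = as.integer(nTimepoints),
    effectRegions = as.integer(effectRegions), effectSize = effectSize,
    effectFraction = effectFraction,
    noiseSd = noiseSd, arCoef = arCoef, spatialDecayMm = spatialDecayMm,
    nuisanceAmplitude = nuisanceAmplitude, seed = as.integer(seed)
  ), class = "CohortSpec")
}

# Standardised AR(1) series: stationary variance 1.
ar1_series <- function(n, phi, innov) {
  x <- numeric(n)
  x[1L] <- innov[1L]
  if (n > 1L) {
    s <- sqrt(1 - phi^2)
    for (t in 2:n) x[t] <- phi * x[t - 1L] + s * innov[t]
  }
  x
}

# Motion-like (slow drifts/sinusoids) + tissue-like (AR(1)) regressors.
make_nuisance <- function(nT, arCoef) {
  t01 <- seq(0, 1, length.out = nT)
  motion <- sapply(1:6, function(q) {
    ph <- runif(1, 0, 2 * pi)
    cy <- runif(1, 0.5, 2.5)
    sin(2 * pi * cy * t01 + ph) + 0.1 * rnorm(nT)
  })
  tissue <- sapply(1:2, function(q) ar1_series(nT, arCoef, rnorm(nT)))
  X <- cbind(motion, tissue)
  colnames(X) <- c(paste0("motion", 1:6), paste0("tissue", 1:2))
  X
}

#' Generate a synthetic two-group cohort on an atlas
#'
#' Each parent region receives a latent AR(1) time series; the latents of
#' different regions share an exponential spatial correlation that decays
#' with inter-centroid distance, so spatially close regions carry similar
#' signal.  Voxel series are the parent latent plus iid Gaussian noise plus
#' a region-weighted mix of nuisance regressors (recorded per subject so
#' [nuisanceRegress()] can remove them exactly at the node level).  In the
#' patient group a shared hub signal is mixed into the latents of
#' `effectRegions`, raising their mutual correlations by about `effectSize`
#' and hence their nodal degree/efficiency relative to controls.
#'
#' @param atlas a [LabelAtlas-class].
#' @param spec a [cohortSpec()].
#' @return A [SyntheticCohort-class]; bitwise-reproducible given
#'   `spec$seed`.
#' @examples
#' atlas <- generateAtlas(c(10, 10, 8), nRegions = 4, seed = 1)
#' spec <- cohortSpec(nPatients = 3, nControls = 3, nTimepoints = 30,
#'                    effectRegions = c(1, 2), effectSize = 0.4)
#' coh <- generateCohort(atlas, spec)
#' coh
#' @export
generateCohort <- function(atlas, spec) {
  stopifnot(is(atlas, "LabelAtlas"), inherits(spec, "CohortSpec"))
  ids <- regionIds(atlas)
  if (!all(spec$effectRegions %in% ids))
    stop("effectRegions must be a subset of the atlas region ids")
  if (length(spec$effectRegions) == 0L && spec$effectSize > 0)
    warning("effectSize > 0 with an empty effect set has no effect")

  dimg <- dim(labelArray(atlas))
  fg <- which(labelArray(atlas) != 0L)
  vox_lab <- as.integer(labelArray(atlas)[fg])
  xyz <- voxel_coords_mm(fg, dimg, voxelSpacing(atlas))
  R <- length(ids)
  nT <- spec$nTimepoints

  # baseline spatial correlation of region latents from centroid distances
  cen <- t(vapply(ids, function(r) colMeans(xyz[vox_lab == r, , drop = FALSE]),
                  numeric(3)))
  D <- as.matrix(stats::dist(cen))
  Sigma <- exp(-D / spec$spatialDecayMm)
  Lc <- t(chol(Sigma))

  region_col <- match(vox_lab, ids)
  eff_idx <- match(spec$effectRegions, ids)
  a <- sqrt(1 - spec$effectSize)
  b <- sqrt(spec$effectSize)

  # focal effect subvolume: the effectFraction of each affected region's
  # voxels nearest its centroid carries the hub signal in patients
  eff_voxel <- logical(length(fg))
  for (r in eff_idx) {
    vr <- which(region_col == r)
    d2c <- rowSums(sweep(xyz[vr, , drop = FALSE], 2L, cen[r, ])^2)
    take <- vr[order(d2c, vr)][seq_len(ceiling(spec$effectFraction *
                                                 length(vr)))]
    eff_voxel[take] <- TRUE
  }

  n <- spec$nPatients + spec$nControls
  group <- factor(rep(c("patient", "control"),
                      c(spec$nPatients, spec$nControls)),
                  levels = c("control", "patient"))
  series <- vector("list", n)
  nuisance <- vector("list", n)
  for (s in seq_len(n)) {
    with_rng(substream_seed(spec$seed, s), {
      innov <- matrix(rnorm(nT * R), nT, R) %*% t(Lc)  # spatially correlated
      lat <- apply(innov, 2L, function(e) ar1_series(nT, spec$arCoef, e))
      latVox <- t(lat[, region_col, drop = FALSE])
      if (group[s] == "patient" && length(eff_idx) && spec$effectSize > 0) {
        hub <- ar1_series(nT, spec$arCoef, rnorm(nT))
        latVox[eff_voxel, ] <- a * latVox[eff_voxel, , drop = FALSE] +
          rep(b * hub, each = sum(eff_voxel))
      }
      X <- make_nuisance(nT, spec$arCoef)
      w <- matrix(rnorm(R * ncol(X), sd = spec$nuisanceAmplitude), R, ncol(X))
      # voxel series: parent latent (hub-mixed in the effect subvolume for
      # patients) + nuisance mix + iid noise
      y <- latVox +
        w[region_col, , drop = FALSE] %*% t(X) +
        matrix(rnorm(length(fg) * nT, sd = spec$noiseSd), length(fg), nT)
      series[[s]] <- y
      nuisance[[s]] <- X
    })
  }
  new("SyntheticCohort", series = series, group = group, nuisance = nuisance,
      truth = spec$effectRegions, atlas = atlas, voxelIndex = fg)
}
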