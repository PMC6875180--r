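# Volume-proportional random-seed region-growing subdivision of a labelled
# atlas into parcellations of approximately N nodes, plus centroid/distance
# utilities.

#' Gray-matter volume fraction per parent region
#'
#' @param atlas a [LabelAtlas-class].
#' @return Data frame with one row per parent region: `region`, `voxels`,
#'   and volume fraction `V` (voxel count over total foreground count;
#'   fractions sum to 1).
#' @export
volumeFractions <- function(atlas) {
  stopifnot(is(atlas, "LabelAtlas"))
  lab <- labelArray(atlas)
  tab <- table(factor(lab[lab != 0L], levels = regionIds(atlas)))
  tot <- sum(tab)
  if (tot == 0L) stop("atlas has an empty foreground")
  data.frame(region = regionIds(atlas), voxels = as.integer(tab),
             V = as.numeric(tab) / tot, row.names = NULL)
}

#' Number of subregions for a region of volume fraction V at scale N
#'
#' `k = V * N`, rounded half-up and floored at 1 so that every parent region
#' survives the subdivision.
#'
#' @param V volume fraction in `(0, 1]`.
#' @param N target total node count (>= 1).
#' @return Integer subregion count.
#' @examples
#' subregionCount(0.0245, 250)  # 6.125 -> 6
#' @export
subregionCount <- function(V, N) {
  stopifnot(all(V > 0), all(V <= 1), N >= 1)
  as.integer(pmax(1, round_half_up(V * N)))
}

# Core region-growing rule on a set of voxel coordinates (mm).
#
# k seed voxels are drawn uniformly without replacement.  Growth then merges,
# at each step, the globally nearest (unassigned voxel, seed) pair by
# Euclidean mm distance -- ties broken by (voxel order, seed index) -- and
# moves that seed to the running mean of all voxel centres merged into it.
# Returns the subregion index (1..k) per voxel.
grow_subregions <- function(xyz, k, seed, seedVoxels = NULL) {
  m <- nrow(xyz)
  if (k > m) stop("k (", k, ") exceeds the region's ", m, " voxels")
  if (k == 1L) return(rep.int(1L, m))
  if (is.null(seedVoxels)) {
    seedVoxels <- with_rng(seed, sample(m, k))
  } else {
    stopifnot(length(seedVoxels) == k, !anyDuplicated(seedVoxels))
  }
  assign <- integer(m)
  assign[seedVoxels] <- seq_len(k)
  centers <- xyz[seedVoxels, , drop = FALSE]
  sizes <- rep.int(1L, k)
  unas <- which(assign == 0L)
  # distance matrix unassigned x seeds; only the merged seed's column moves
  d2 <- matrix(0, length(unas), k)
  for (s in seq_len(k)) {
    d2[, s] <- (xyz[unas, 1L] - centers[s, 1L])^2 +
      (xyz[unas, 2L] - centers[s, 2L])^2 +
      (xyz[unas, 3L] - centers[s, 3L])^2
  }
  while (length(unas)) {
    mn <- min(d2)
    hit <- which(d2 <= mn + 1e-12, arr.ind = TRUE)
    # deterministic tie-break: smallest voxel position, then seed index
    hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
    vi <- hit[1L, 1L]; s <- hit[1L, 2L]
    v <- unas[vi]
    assign[v] <- s
    centers[s, ] <- (centers[s, ] * sizes[s] + xyz[v, ]) / (sizes[s] + 1L)
    sizes[s] <- sizes[s] + 1L
    unas <- unas[-vi]
    d2 <- d2[-vi, , drop = FALSE]
    if (length(unas)) {
      d2[, s] <- (xyz[unas, 1L] - centers[s, 1L])^2 +
        (xyz[unas, 2L] - centers[s, 2L])^2 +
        (xyz[unas, 3L] - centers[s, 3L])^2
    }
  }
  assign
}

#' Subdivide one parent region into k subregions
#'
#' Implements seeded region growing: `k` random seed voxels are drawn in the
#' region, then the globally nearest (unassigned voxel, seed) pair is merged
#' repeatedly, re-centring the seed on the running physical mean of its
#' voxels, until the region is exhausted.  Produces exactly `k` nonempty,
#' disjoint subregions covering the region.
#'
#' @param atlas a [LabelAtlas-class].
#' @param region parent region id.
#' @param k number of subregions (`<=` region voxel count).
#' @param seed RNG seed for the random seed voxels.
#' @param seedVoxels optional explicit seed voxel positions (indices into the
#'   region's voxel list, in atlas linear-index order) overriding the random
#'   draw; intended for reproducing a published seed set or for testing.
#' @return Integer vector: subregion index (1..k) for each region voxel, in
#'   increasing atlas linear-index order.
#' @export
subdivideRegion <- function(atlas, region, k, seed = 1, seedVoxels = NULL) {
  stopifnot(is(atlas, "LabelAtlas"), region %in% regionIds(atlas))
  idx <- which(labelArray(atlas) == region)
  xyz <- voxel_coords_mm(idx, dim(labelArray(atlas)), voxelSpacing(atlas))
  grow_subregions(xyz, as.integer(k), seed, seedVoxels)
}

#' Subdivide a whole atlas into approximately N nodes
#'
#' Each parent region is independently subdivided into
#' `subregionCount(V, N)` subregions ([subdivideRegion()]); voxels of
#' adjacent parent regions are never merged, so the subdivision respects the
#' original region boundaries.  Because per-region counts are rounded, the
#' achieved node count can deviate slightly from `N`.  Subregions are
#' relabelled `1:achievedN` in (parent id, creation order).  The per-region
#' RNG stream is namespaced by region id, so results do not depend on region
#' iteration order.
#'
#' @param atlas a [LabelAtlas-class].
#' @param N expected total node count (>= number of parent regions).
#' @param seed RNG seed.
#' @return A [ParcellationScheme-class].
#' @examples
#' atlas <- generateAtlas(c(12, 12, 10), nRegions = 5, seed = 1)
#' parc <- subdivideAtlas(atlas, N = 20, seed = 42)
#' achievedN(parc)
#' @export
subdivideAtlas <- function(atlas, N, seed = 1) {
  stopifnot(is(atlas, "LabelAtlas"))
  vf <- volumeFractions(atlas)
  if (N < nrow(vf))
    stop("N (", N, ") is below the number of parent regions (", nrow(vf), ")")
  k_per <- subregionCount(vf$V, N)
  dimg <- dim(labelArray(atlas))
  out <- array(0L, dim = dimg)
  parent_of <- integer(0)
  cents <- NULL
  next_id <- 1L
  for (r in seq_len(nrow(vf))) {
    reg <- vf$region[r]
    idx <- which(labelArray(atlas) == reg)
    xyz <- voxel_coords_mm(idx, dimg, voxelSpacing(atlas))
    sub <- grow_subregions(xyz, k_per[r], substream_seed(seed, reg))
    ids_here <- next_id + seq_len(k_per[r]) - 1L
    out[idx] <- ids_here[sub]
    parent_of <- c(parent_of, rep.int(as.integer(reg), k_per[r]))
    cen <- t(vapply(seq_len(k_per[r]), function(s)
      colMeans(xyz[sub == s, , drop = FALSE]), numeric(3)))
    cents <- rbind(cents, cen)
    next_id <- next_id + k_per[r]
  }
  achieved <- next_id - 1L
  names(parent_of) <- seq_len(achieved)
  rownames(cents) <- seq_len(achieved)
  colnames(cents) <- c("x", "y", "z")
  new("ParcellationScheme", labels = out, parentOf = parent_of,
      targetN = as.integer(N), achievedN = achieved, centroids = cents,
      spacing = voxelSpacing(atlas), seed = as.integer(seed))
}

#' Pairwise Euclidean centroid distances between nodes
#'
#' @param parc a [ParcellationScheme-class].
#' @return Symmetric achievedN x achievedN matrix of centroid distances (mm),
#'   zero diagonal.
#' @export
centroidDistances <- function(parc) {
  stopifnot(is(parc, "ParcellationScheme"))
  as.matrix(stats::dist(nodeCentroids(parc)))
}
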