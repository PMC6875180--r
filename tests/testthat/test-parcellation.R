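# Volume-proportional seeded region-growing subdivision.

make_two_region_atlas <- function(n1, n2) {
  # a 1D ribbon: first n1 voxels region 1, next n2 region 2
  lab <- array(0L, dim = c(n1 + n2, 1, 1))
  lab[seq_len(n1), 1, 1] <- 1L
  lab[n1 + seq_len(n2), 1, 1] <- 2L
  LabelAtlas(lab, spacing = c(3, 3, 3))
}

test_that("volumeFractions are voxel-count proportions summing to one", {
  vf <- volumeFractions(make_two_region_atlas(50, 50))
  expect_equal(vf$V, c(0.5, 0.5))
  vf <- volumeFractions(make_two_region_atlas(30, 70))
  expect_equal(vf$V, c(0.3, 0.7))
  vf <- volumeFractions(tiny_atlas(7))
  expect_equal(sum(vf$V), 1, tolerance = 1e-9)
  expect_true(all(vf$V > 0))
})

test_that("subregionCount rounds half-up and floors at one", {
  expect_identical(subregionCount(0.01, 1000), 10L)
  expect_identical(subregionCount(0.0245, 250), 6L)   # 6.125 -> 6
  expect_identical(subregionCount(0.001, 90), 1L)     # 0.09 -> 0 -> floor 1
  expect_identical(subregionCount(0.025, 100), 3L)    # 2.5 rounds up
})

test_that("subdivideRegion k=1 returns the whole region", {
  atlas <- tiny_atlas(3, shape = c(8, 8, 8))
  idx <- which(labelArray(atlas) == 2L)
  expect_identical(subdivideRegion(atlas, 2L, k = 1), rep.int(1L, length(idx)))
})

test_that("growth on a 1D row with end seeds yields two contiguous halves", {
  lab <- array(0L, dim = c(10, 1, 1)); lab[, 1, 1] <- 1L
  atlas <- LabelAtlas(lab, spacing = c(3, 3, 3))
  # hand-simulated growth rule: alternating merges from both ends
  out <- subdivideRegion(atlas, 1L, k = 2, seedVoxels = c(1L, 10L))
  expect_identical(out, rep(c(1L, 2L), each = 5))
})

test_that("subdivideRegion errors when k exceeds the voxel count", {
  atlas <- make_two_region_atlas(5, 5)
  expect_error(subdivideRegion(atlas, 1L, k = 6), "exceeds")
})

test_that("subdivideAtlas at N = parent count is a bijective relabeling", {
  atlas <- tiny_atlas(5)
  parc <- subdivideAtlas(atlas, N = 5, seed = 9)
  expect_identical(achievedN(parc), 5L)
  # every subregion exactly matches one parent's voxel set
  for (r in regionIds(atlas)) {
    sub <- unique(labelArray(parc)[labelArray(atlas) == r])
    expect_length(sub, 1L)
    expect_identical(as.integer(parentOf(parc)[[as.character(sub)]]), r)
  }
})

test_that("two equal parents at N=10 give 5 subregions each", {
  atlas <- make_two_region_atlas(40, 40)
  parc <- subdivideAtlas(atlas, N = 10, seed = 4)
  expect_identical(achievedN(parc), 10L)
  expect_identical(as.integer(table(parentOf(parc))), c(5L, 5L))
  # partition check within each parent
  for (r in 1:2) {
    voxSub <- labelArray(parc)[labelArray(atlas) == r]
    expect_true(all(voxSub != 0L))
    expect_identical(length(unique(voxSub)), 5L)
  }
})

test_that("parcellation invariants hold across seeds and scales", {
  atlas <- tiny_atlas(6)
  nParents <- length(regionIds(atlas))
  prevN <- 0L
  for (N in c(6L, 15L, 30L)) {
    parc <- subdivideAtlas(atlas, N, seed = 21)
    lab <- labelArray(parc)
    # partition: subregions cover exactly the foreground
    expect_identical(which(lab != 0L), which(labelArray(atlas) != 0L))
    # boundary respect: each subregion lies in a single parent
    pairs <- unique(cbind(sub = as.integer(lab[lab != 0L]),
                          par = as.integer(labelArray(atlas)[lab != 0L])))
    expect_identical(nrow(pairs), as.integer(achievedN(parc)))
    expect_identical(unname(parentOf(parc)[as.character(pairs[, "sub"])]),
                     as.integer(pairs[, "par"]))
    # monotone scale
    expect_gte(achievedN(parc), prevN)
    prevN <- achievedN(parc)
    # rounding-error bound on the achieved node count
    expect_lte(abs(achievedN(parc) - N), nParents / 2)
  }
  # determinism under a fixed seed
  p1 <- subdivideAtlas(atlas, 15, seed = 33)
  p2 <- subdivideAtlas(atlas, 15, seed = 33)
  expect_identical(labelArray(p1), labelArray(p2))
  expect_identical(nodeCentroids(p1), nodeCentroids(p2))
})

test_that("subdivideAtlas rejects N below the parent count", {
  atlas <- tiny_atlas(6)
  expect_error(subdivideAtlas(atlas, N = 3), "below the number")
})

test_that("centroid distances are Euclidean, symmetric and match per-pair oracle", {
  atlas <- tiny_atlas(4)
  parc <- subdivideAtlas(atlas, N = 8, seed = 5)
  n <- achievedN(parc)
  D <- centroidDistances(parc)
  expect_identical(dim(D), c(n, n))
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, n))
  cen <- nodeCentroids(parc)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    expect_equal(D[i, j], sqrt(sum((cen[i, ] - cen[j, ])^2)), tolerance = 1e-12)
  }
})

test_that("a 3-4-5 centroid pair is 5 mm apart", {
  parc <- new("ParcellationScheme",
    labels = array(c(1L, 2L), dim = c(2, 1, 1)),
    parentOf = c(`1` = 1L, `2` = 1L), targetN = 2L, achievedN = 2L,
    centroids = matrix(c(0, 0, 0, 3, 4, 0), 2, 3, byrow = TRUE,
                       dimnames = list(1:2, c("x", "y", "z"))),
    spacing = c(1, 1, 1), seed = 1L)
  expect_equal(centroidDistances(parc)[1, 2], 5)
})
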