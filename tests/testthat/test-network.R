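# Node-mean extraction, nuisance regression, correlation, thresholding.

test_that("extractNodeSeries averages voxels within each node", {
  lab <- array(0L, dim = c(4, 1, 1)); lab[, 1, 1] <- c(1L, 1L, 2L, 2L)
  atlas <- LabelAtlas(lab)
  parc <- subdivideAtlas(atlas, N = 2, seed = 1)
  x <- rbind(c(1, 1, 1), c(3, 3, 3), c(5, 6, 7), c(5, 6, 7))
  ns <- extractNodeSeries(x, parc, voxelIndex = which(lab != 0L))
  # node covering voxels (1,1,1)/(3,3,3) -> (2,2,2); identical voxels -> same
  expect_true(any(apply(ns, 1, function(r) all(r == c(2, 2, 2)))))
  expect_true(any(apply(ns, 1, function(r) all(r == c(5, 6, 7)))))

  # brute-force voxel loop oracle on a random 3-node toy volume
  lab3 <- array(0L, dim = c(6, 1, 1)); lab3[, 1, 1] <- c(1L, 1L, 2L, 3L, 3L, 3L)
  atlas3 <- LabelAtlas(lab3)
  parc3 <- subdivideAtlas(atlas3, N = 3, seed = 1)
  set.seed(42)
  y <- matrix(rnorm(6 * 5), 6, 5)
  ns3 <- extractNodeSeries(y, parc3, voxelIndex = which(lab3 != 0L))
  nodeOfVox <- as.integer(labelArray(parc3)[which(lab3 != 0L)])
  for (nd in 1:3) for (t in 1:5) {
    acc <- 0; cnt <- 0
    for (v in 1:6) if (nodeOfVox[v] == nd) { acc <- acc + y[v, t]; cnt <- cnt + 1 }
    expect_equal(ns3[nd, t], acc / cnt, tolerance = 1e-12)
  }
})

test_that("cohort-level node series match the per-subject matrix route", {
  atlas <- tiny_atlas(4, shape = c(8, 8, 8))
  coh <- generateCohort(atlas, cohortSpec(2, 2, 20, seed = 2))
  parc <- subdivideAtlas(atlas, N = 8, seed = 3)
  ns <- extractNodeSeries(coh, parc)
  expect_length(ns, 4L)
  one <- extractNodeSeries(subjectSeries(coh)[[2]], parc, coh@voxelIndex)
  expect_equal(ns[[2]], one)
})

test_that("nuisanceRegress removes the regressors exactly", {
  set.seed(1)
  nT <- 20
  y <- matrix(rnorm(3 * nT), 3, nT)
  # intercept only: centering
  res <- nuisanceRegress(y, matrix(numeric(0), nT, 0))
  expect_equal(res, y - rowMeans(y), tolerance = 1e-12)
  # series equal to a regressor: residual ~ 0
  X <- matrix(rnorm(nT * 3), nT, 3)
  res <- nuisanceRegress(rbind(X[, 2]), X)
  expect_lt(sqrt(sum(res^2)), 1e-8 * sqrt(sum(X[, 2]^2)))
  # normal-equations oracle
  res <- nuisanceRegress(y, X)
  Xi <- cbind(1, X)
  beta <- solve(t(Xi) %*% Xi, t(Xi) %*% t(y))
  expect_equal(res, y - t(Xi %*% beta), tolerance = 1e-10)
  # residuals orthogonal to regressors
  expect_lt(max(abs(res %*% Xi)), 1e-8)
  # idempotence
  expect_equal(nuisanceRegress(res, X), res, tolerance = 1e-10)
})

test_that("nuisanceRegress names collinear columns", {
  nT <- 20
  X <- cbind(a = rnorm(nT), b = rnorm(nT))
  X <- cbind(X, c = X[, "a"] + X[, "b"])
  expect_error(nuisanceRegress(matrix(rnorm(nT), 1), X), "collinear")
})

test_that("correlationMatrix matches its definitional oracle", {
  set.seed(3)
  y <- matrix(rnorm(4 * 10), 4, 10)
  y[2, ] <- y[1, ]          # duplicate -> r = 1
  y[3, ] <- -y[1, ]         # sign flip -> r = -1
  r <- correlationMatrix(y)
  expect_equal(r[1, 2], 1)
  expect_equal(r[1, 3], -1)
  # explicit covariance / SD ratio for every pair
  for (i in 1:4) for (j in 1:4) {
    a <- y[i, ] - mean(y[i, ]); b <- y[j, ] - mean(y[j, ])
    expect_equal(r[i, j], sum(a * b) / sqrt(sum(a^2) * sum(b^2)),
                 tolerance = 1e-12)
  }
  expect_true(all(abs(r) <= 1 + 1e-12))
  # affine rescaling of one node leaves correlations unchanged
  y2 <- y; y2[4, ] <- 5 * y[4, ] - 2
  expect_equal(correlationMatrix(y2), r, tolerance = 1e-12)
  # zero-variance node is reported
  y[2, ] <- 1
  expect_error(correlationMatrix(y), "zero-variance.*2")
})

test_that("thresholdBySparsity keeps the strongest upper-triangle entries", {
  set.seed(4)
  corr <- matrix(0, 4, 4); diag(corr) <- 1
  vals <- c(0.9, 0.1, 0.7, -0.3, 0.5, 0.2)
  corr[upper.tri(corr)] <- vals
  corr[lower.tri(corr)] <- t(corr)[lower.tri(corr)]
  full <- thresholdBySparsity(corr, 1)
  expect_identical(attr(full, "edges"), 6L)
  top2 <- thresholdBySparsity(corr, 1 / 3)
  expect_identical(attr(top2, "edges"), 2L)
  # top-2 signed entries are 0.9 (1,2) and 0.7 (1,4) in this layout
  ut <- which(upper.tri(corr), arr.ind = TRUE)
  kept <- ut[order(-vals)[1:2], , drop = FALSE]
  for (e in seq_len(2)) expect_identical(top2[kept[e, 1], kept[e, 2]], 1L)
  expect_equal(sum(top2) / 2, 2)
  # achieved sparsity within one edge of target
  for (S in c(0.2, 0.5, 0.8)) {
    adj <- thresholdBySparsity(corr, S)
    expect_lte(abs(attr(adj, "sparsity") - S), 1 / 6)
  }
  expect_warning(thresholdBySparsity(corr, 0.01), "no edges")
})

test_that("edge sets are nested across increasing sparsity", {
  set.seed(5)
  y <- matrix(rnorm(12 * 40), 12, 40)
  corr <- correlationMatrix(y)
  grid <- sparsityGrid()
  prev <- NULL
  for (S in grid) {
    adj <- thresholdBySparsity(corr, S)
    if (!is.null(prev)) expect_true(all(adj[prev == 1L] == 1L))
    prev <- adj
  }
})

test_that("sparsityGrid builds valid strictly increasing grids", {
  g <- sparsityGrid()
  expect_equal(g, c(0.08, 0.13, 0.18, 0.23, 0.28))
  expect_equal(sparsityGrid(0.1, 0.1), 0.1)
  expect_error(sparsityGrid(by = 0), "positive")
  expect_error(sparsityGrid(0.3, 0.1), ">=")
  g2 <- sparsityGrid(0.05, 0.4, 0.07)
  expect_true(all(diff(g2) > 0))
  expect_true(all(g2 >= 0.05 & g2 <= 0.4))
})
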