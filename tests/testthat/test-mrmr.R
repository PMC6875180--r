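# Mutual information, Table-style D/R/MID scores and redundancy analyses.

test_that("discretizeFeatures applies the mean +/- alpha*SD rule", {
  x <- cbind(f1 = c(0, 10, -10))
  st <- discretizeFeatures(x, alpha = 0.5)
  expect_identical(as.integer(st), c(0L, 1L, -1L))
  # location-scale invariance
  st2 <- discretizeFeatures(7 * x + 3, alpha = 0.5)
  expect_identical(as.integer(st2), as.integer(st))
  expect_warning(stc <- discretizeFeatures(cbind(c(2, 2, 2))), "constant")
  expect_identical(as.integer(stc), c(0L, 0L, 0L))
  expect_error(discretizeFeatures(x, alpha = 0), "positive")
})

test_that("mutualInformation matches hand-enumerated joint tables", {
  expect_equal(mutualInformation(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(mutualInformation(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)
  # joint table of a=(0,0,1,1), b=(0,0,0,1): p(1,1)=1/4, p(1,0)=1/4,
  # p(0,0)=1/2; I = sum p log2 p/(pa pb)
  hand <- 0.5 * log2(0.5 / (0.5 * 0.75)) + 0.25 * log2(0.25 / (0.5 * 0.75)) +
    0.25 * log2(0.25 / (0.5 * 0.25))
  expect_equal(mutualInformation(c(0, 0, 1, 1), c(0, 0, 0, 1)), hand,
               tolerance = 1e-12)
  # symmetry, nonnegativity, relabeling invariance, nats option
  set.seed(13)
  a <- sample(c(-1, 0, 1), 30, replace = TRUE)
  b <- sample(c(-1, 0, 1), 30, replace = TRUE)
  expect_equal(mutualInformation(a, b), mutualInformation(b, a))
  expect_gte(mutualInformation(a, b), 0)
  relab <- c(`-1` = 5, `0` = 9, `1` = 2)[as.character(a)]
  expect_equal(mutualInformation(relab, b), mutualInformation(a, b))
  expect_equal(mutualInformation(a, b, unit = "nats"),
               mutualInformation(a, b) * log(2))
  expect_error(mutualInformation(1:3, 1:4), "equal length")
})

test_that("table2Scores evaluates D, R and MID literally", {
  set.seed(14)
  n <- 40
  h <- factor(rep(c("control", "patient"), each = n / 2))
  x <- cbind(rnorm(n), rnorm(n), rnorm(n) + 2 * (as.integer(h) - 1))
  disc <- discretizeFeatures(x, alpha = 0.5)
  # singleton subset: D = I(h,i), R = H(i), MID = D - H
  s1 <- table2Scores(disc, h, subset = 3)
  expect_equal(s1[["D"]], mutualInformation(h, disc[, 3]))
  expect_equal(s1[["R"]], mutualInformation(disc[, 3], disc[, 3]))
  expect_equal(s1[["MID"]], s1[["D"]] - s1[["R"]], tolerance = 1e-12)
  # label empirically independent of a feature: D contributes 0
  ind <- rep(c(-1L, 1L), n / 2)  # balanced within each group
  disc2 <- cbind(disc, ind)
  s2 <- table2Scores(disc2, h, subset = 4)
  expect_equal(s2[["D"]], 0)
  expect_equal(s2[["MID"]], -s2[["R"]])
  # identity holds for any subset
  s3 <- table2Scores(disc, h, subset = c(1, 2, 3))
  expect_equal(s3[["MID"]] + s3[["R"]] - s3[["D"]], 0, tolerance = 1e-12)
  # R includes the i = j self-information terms as the set formula is written
  rOff <- mean(redundancyMatrix(disc, 1:3)[upper.tri(diag(3))])
  expect_gt(s3[["R"]], 0)
  ents <- vapply(1:3, function(i) mutualInformation(disc[, i], disc[, i]), 0)
  expect_equal(s3[["R"]],
               (sum(ents) + 2 * rOff * 3) / 9, tolerance = 1e-12)
  expect_error(table2Scores(disc, h, integer(0)), "nonempty")
})

test_that("perFeatureMid penalises an exact duplicate by its entropy", {
  set.seed(15)
  n <- 40
  h <- factor(rep(c("control", "patient"), each = n / 2))
  good <- rnorm(n) + 1.5 * (as.integer(h) - 1)
  x <- cbind(a = good, b = good, c = rnorm(n))
  disc <- discretizeFeatures(x, alpha = 0.5)
  out <- perFeatureMid(disc, h)
  first <- out$order[1]
  expect_true(first %in% 1:2)  # one of the duplicated informative columns
  dup <- setdiff(1:2, first)
  rel <- mutualInformation(h, disc[, dup])
  Hdup <- mutualInformation(disc[, dup], disc[, dup])
  # when the copy is scored, its redundancy term includes I(copy, original)=H
  expect_lte(out$score[dup], rel - Hdup / 2 + 1e-12)
  # single feature: score is the bare relevance
  one <- perFeatureMid(disc[, 1, drop = FALSE], h)
  expect_equal(one$score, mutualInformation(h, disc[, 1]))
  # scores are invariant to column order (distinct-valued features)
  set.seed(16)
  x2 <- matrix(rnorm(n * 4), n)
  d2 <- discretizeFeatures(x2, alpha = 0.5)
  perm <- c(3, 1, 4, 2)
  o1 <- perFeatureMid(d2, h)
  o2 <- perFeatureMid(d2[, perm], h)
  expect_equal(o2$score, o1$score[perm], tolerance = 1e-12)
})

test_that("subsetMidCurve averages scores over P-ranked prefixes", {
  set.seed(17)
  n <- 30
  h <- factor(rep(c("control", "patient"), each = n / 2))
  disc <- discretizeFeatures(matrix(rnorm(n * 7), n), alpha = 0.5)
  rk <- sample(7)
  crv <- subsetMidCurve(disc, h, rk, step = 3)
  score <- perFeatureMid(disc, h)$score
  expect_equal(crv$nFeatures, c(3L, 6L, 7L))
  expect_equal(crv$meanMID[3], mean(score))
  expect_equal(crv$meanMID[1], mean(score[rk[1:3]]))
  # step beyond the feature count -> single point
  big <- subsetMidCurve(disc, h, rk, step = 50)
  expect_identical(nrow(big), 1L)
  expect_error(subsetMidCurve(disc, h, rk, step = 0), "positive")
  expect_error(subsetMidCurve(disc, h, 1:3), "permutation")
})

test_that("redundancyMatrix is symmetric and matches pairwise calls", {
  set.seed(18)
  n <- 30
  x <- matrix(rnorm(n * 4), n)
  x[, 2] <- x[, 1]
  disc <- discretizeFeatures(x, alpha = 0.5)
  m <- redundancyMatrix(disc, 1:4)
  expect_true(all(is.na(diag(m))))
  expect_equal(m, t(m))
  expect_equal(m[1, 2], mutualInformation(disc[, 1], disc[, 1]))  # duplicate
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(m[i, j], mutualInformation(disc[, i], disc[, j]))
  expect_error(redundancyMatrix(disc, 1), "at least 2")
})

test_that("redundancy-distance regression recovers exact linear data", {
  d <- matrix(0, 4, 4)
  d[upper.tri(d)] <- c(1, 2, 3, 4, 5, 6)
  d <- d + t(d)
  r <- 2 - 0.3 * d; diag(r) <- NA
  fit <- suppressWarnings(redundancyDistanceRegression(r, d))  # exact fit
  expect_equal(fit$slope, -0.3, tolerance = 1e-10)
  expect_equal(fit$adjR2, 1, tolerance = 1e-8)
  expect_error(redundancyDistanceRegression(r[1:2, 1:2], d[1:2, 1:2]),
               "3 usable pairs")
})

test_that("same-node feature pairs are excluded from distance pairs", {
  atlas <- tiny_atlas(3, shape = c(8, 8, 8))
  coh <- generateCohort(atlas, cohortSpec(2, 2, 30, seed = 4))
  tab <- buildFeatureTable(coh, subdivideAtlas(atlas, 3, seed = 1),
                           grid = c(0.4, 0.7))
  # features 1..3 are degree of nodes 1..3; feature 4 is betweenness node 1
  d <- featurePairDistances(tab, c(1, 2, 4))
  expect_true(is.na(d["4", "1"]))  # same node, different metric
  expect_false(is.na(d["1", "2"]))
  cen <- as.data.frame(SummarizedExperiment::rowData(tab))[1:2,
                                                           c("cx", "cy", "cz")]
  expect_equal(d["1", "2"],
               sqrt(sum((as.numeric(cen[1, ]) - as.numeric(cen[2, ]))^2)))
})
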