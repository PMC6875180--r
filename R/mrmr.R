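# Minimum-redundancy-maximum-relevance feature evaluation on discretized
# features: mutual information, set-level D / R / MID scores, incremental
# per-feature effectiveness, pairwise redundancy, and the
# redundancy-vs-distance regression.

#' Discretize features into three states
#'
#' Per feature, values below `mean - alpha * SD` map to state -1, above
#' `mean + alpha * SD` to +1, and to 0 otherwise -- the usual binning for
#' mutual-information feature scoring.  Discretization is location-scale
#' invariant.  Constant features map to all-0 with a warning.
#'
#' @param x subjects x features numeric matrix, or an
#'   [AUCFeatureTable-class] (features are transposed to columns).
#' @param alpha positive bin half-width in SD units (default 1).
#' @return Integer matrix of states with attributes `mean`, `sd`, `alpha`
#'   recording the binning.
#' @export
discretizeFeatures <- function(x, alpha = 1) {
  if (alpha <= 0) stop("alpha must be positive")
  if (is(x, "AUCFeatureTable")) x <- t(SummarizedExperiment::assay(x, "auc"))
  x <- as.matrix(x)
  mu <- colMeans(x)
  sd <- apply(x, 2L, stats::sd)
  if (any(sd == 0 | !is.finite(sd))) {
    warning("constant feature(s) mapped to state 0: ",
            paste(which(sd == 0 | !is.finite(sd)), collapse = ", "))
  }
  st <- matrix(0L, nrow(x), ncol(x), dimnames = dimnames(x))
  for (j in seq_len(ncol(x))) {
    if (sd[j] > 0 && is.finite(sd[j])) {
      st[x[, j] < mu[j] - alpha * sd[j], j] <- -1L
      st[x[, j] > mu[j] + alpha * sd[j], j] <- 1L
    }
  }
  structure(st, mean = mu, sd = sd, alpha = alpha)
}

#' Plug-in mutual information of two discrete variables
#'
#' `I(A, B) = sum p(a, b) log[p(a, b) / (p(a) p(b))]` over the observed
#' states of the empirical joint table, with `0 log 0 = 0`.
#'
#' @param a,b equal-length vectors of discrete states (any atomic type).
#' @param unit `"bits"` (log2, default) or `"nats"`.
#' @return Nonnegative scalar; `mutualInformation(x, x)` is the entropy of
#'   `x`.
#' @export
mutualInformation <- function(a, b, unit = c("bits", "nats")) {
  unit <- match.arg(unit)
  if (length(a) != length(b)) stop("a and b must have equal length")
  j <- table(a, b) / length(a)
  pa <- rowSums(j); pb <- colSums(j)
  nz <- j > 0
  ratio <- j / outer(pa, pb)
  mi <- sum(j[nz] * log(ratio[nz]))
  mi <- max(mi, 0)  # clip tiny negative rounding
  if (unit == "bits") mi / log(2) else mi
}

#' Set-level relevance, redundancy and MID for a feature subset
#'
#' Literal evaluation of the mRMR set scores: relevance
#' `D = (1/|S|) sum_{i in S} I(h, i)` (mean mutual information between each
#' feature and the group label h), redundancy
#' `R = (1/|S|^2) sum_{i,j in S} I(i, j)` (the double sum includes the
#' `i = j` self-information terms, as the set formula is written), and
#' `MID = D - R`.
#'
#' @param disc discretized features from [discretizeFeatures()].
#' @param labels group factor/vector, one per subject.
#' @param subset column indices of the feature subset (nonempty).
#' @param unit `"bits"` or `"nats"`.
#' @return Named numeric vector `D`, `R`, `MID` (with `MID = D - R` to
#'   machine precision).
#' @export
table2Scores <- function(disc, labels, subset, unit = c("bits", "nats")) {
  unit <- match.arg(unit)
  if (!length(subset)) stop("subset must be nonempty")
  S <- as.integer(subset)
  D <- mean(vapply(S, function(i)
    mutualInformation(labels, disc[, i], unit), 0))
  R <- 0
  for (i in S) for (j in S)
    R <- R + mutualInformation(disc[, i], disc[, j], unit)
  R <- R / length(S)^2
  c(D = D, R = R, MID = D - R)
}

#' Incremental per-feature mRMR effectiveness scores
#'
#' Greedy mRMR selection: the first selected feature scores its relevance
#' `I(h, i)`; each subsequent candidate scores
#' `I(h, i) - (1/|sel|) sum_{j in sel} I(i, j)` and the candidate with the
#' largest score is selected.  Every feature keeps the score it had at its
#' own selection step, so an exact duplicate of an already-selected feature
#' is penalised by its full self-information.
#'
#' @param disc discretized features from [discretizeFeatures()].
#' @param labels group factor/vector.
#' @param unit `"bits"` or `"nats"`.
#' @return List: `score` (per-feature, original column order) and `order`
#'   (selection order, feature indices).
#' @export
perFeatureMid <- function(disc, labels, unit = c("bits", "nats")) {
  unit <- match.arg(unit)
  nf <- ncol(disc)
  if (nf < 1L) stop("need at least one feature")
  rel <- vapply(seq_len(nf), function(i)
    mutualInformation(labels, disc[, i], unit), 0)
  score <- numeric(nf)
  selected <- integer(0)
  remaining <- seq_len(nf)
  redsum <- numeric(nf)  # sum of I(i, j) over selected j, per candidate i
  while (length(remaining)) {
    cand <- if (length(selected) == 0L) rel[remaining] else
      rel[remaining] - redsum[remaining] / length(selected)
    pick <- remaining[which.max(cand)]  # ties -> lowest feature index
    score[pick] <- max(cand)
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
    for (i in remaining)
      redsum[i] <- redsum[i] + mutualInformation(disc[, i], disc[, pick], unit)
  }
  list(score = score, order = selected)
}

#' Mean per-feature MID along growing P-ranked prefixes
#'
#' Features are sorted by screening P value (ascending) and prefixes grown
#' in blocks of `step`; for each prefix the mean of the per-feature
#' incremental MID scores ([perFeatureMid()]) over its members is reported.
#'
#' @param disc discretized features.
#' @param labels group factor/vector.
#' @param pRanking feature indices in ascending-P order, covering all
#'   features.
#' @param step prefix growth step (default 3).
#' @param unit `"bits"` or `"nats"`.
#' @return Data frame with `nFeatures` and `meanMID`.
#' @export
subsetMidCurve <- function(disc, labels, pRanking, step = 3,
                           unit = c("bits", "nats")) {
  if (step <= 0) stop("step must be positive")
  nf <- ncol(disc)
  if (length(pRanking) != nf || !setequal(pRanking, seq_len(nf)))
    stop("pRanking must be a permutation of all feature indices")
  score <- perFeatureMid(disc, labels, unit)$score
  sizes <- as.integer(unique(c(seq(min(step, nf), nf, by = step), nf)))
  meanMID <- vapply(sizes, function(s)
    mean(score[pRanking[seq_len(s)]]), 0)
  data.frame(nFeatures = sizes, meanMID = meanMID)
}

#' Pairwise redundancy matrix of a feature subset
#'
#' Mutual information between every pair of distinct subset features;
#' self-pairs are excluded from the report (diagonal `NA`).
#'
#' @param disc discretized features.
#' @param subset column indices, size >= 2.
#' @param unit `"bits"` or `"nats"`.
#' @return Symmetric matrix with `NA` diagonal, dimnames = subset indices.
#' @export
redundancyMatrix <- function(disc, subset, unit = c("bits", "nats")) {
  unit <- match.arg(unit)
  S <- as.integer(subset)
  if (length(S) < 2L) stop("subset must contain at least 2 features")
  m <- matrix(NA_real_, length(S), length(S),
              dimnames = list(S, S))
  for (i in seq_along(S)) for (j in seq_along(S)) if (i < j) {
    m[i, j] <- m[j, i] <- mutualInformation(disc[, S[i]], disc[, S[j]], unit)
  }
  m
}

#' Centroid distances between the nodes of a feature subset
#'
#' Distance for a feature pair is the Euclidean centroid distance between
#' the two features' nodes.  Pairs of features on the same node (different
#' metrics, distance 0) are degenerate for the distance regression and are
#' returned as `NA`.
#'
#' @param table an [AUCFeatureTable-class].
#' @param subset feature indices.
#' @return Symmetric matrix of distances (mm) aligned with `subset`;
#'   same-node pairs and the diagonal are `NA`.
#' @export
featurePairDistances <- function(table, subset) {
  rd <- SummarizedExperiment::rowData(table)[subset, , drop = FALSE]
  cen <- cbind(rd$cx, rd$cy, rd$cz)
  d <- as.matrix(stats::dist(cen))
  same <- outer(rd$node, rd$node, "==")
  d[same] <- NA_real_
  diag(d) <- NA_real_
  dimnames(d) <- list(subset, subset)
  d
}

#' Regress pairwise redundancy on inter-node distance
#'
#' Ordinary least squares of the pairwise mutual information of a feature
#' subset on the Euclidean distance between the corresponding node
#' centroids.  Adjusted R-squared is `1 - (1 - R2)(n - 1)/(n - 2)`.
#'
#' @param redundancy symmetric MI matrix from [redundancyMatrix()].
#' @param distance symmetric distance matrix aligned pair-for-pair (e.g.
#'   [featurePairDistances()]); `NA` pairs are dropped.
#' @return List: `slope`, `adjR2`, `p` (two-sided slope P), `n` (pairs
#'   used).
#' @export
redundancyDistanceRegression <- function(redundancy, distance) {
  stopifnot(identical(dim(redundancy), dim(distance)))
  ut <- upper.tri(redundancy)
  r <- redundancy[ut]; d <- distance[ut]
  keep <- is.finite(r) & is.finite(d)
  if (sum(keep) < 3L) stop("need at least 3 usable pairs")
  fit <- summary(stats::lm(r[keep] ~ d[keep]))
  list(slope = unname(stats::coef(fit)[2L, 1L]),
       adjR2 = fit$adj.r.squared,
       p = unname(stats::coef(fit)[2L, 4L]),
       n = sum(keep))
}

#' Linear regression of per-feature MID on screening P value
#'
#' Summarises whether small-P (highly discriminative) features also carry
#' high mRMR effectiveness.
#'
#' @param screen result of [screenFeatures()].
#' @param midScore per-feature scores from [perFeatureMid()] (the `score`
#'   element), aligned with the screen's feature order.
#' @return List: `slope`, `adjR2`, `p`.
#' @export
pMidRegression <- function(screen, midScore) {
  stopifnot(length(midScore) == nrow(screen))
  fit <- summary(stats::lm(midScore ~ screen$p))
  list(slope = unname(stats::coef(fit)[2L, 1L]),
       adjR2 = fit$adj.r.squared,
       p = unname(stats::coef(fit)[2L, 4L]))
}
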