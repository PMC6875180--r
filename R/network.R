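# Per-subject correlation networks: node-mean extraction, nuisance
# regression, Pearson correlation, and proportional sparsity thresholding.

node_means <- function(series, nodeLab, nNodes) {
  # series: voxel x time; nodeLab: node id per row
  cnt <- tabulate(nodeLab, nbins = nNodes)
  if (any(cnt == 0L))
    stop("subregion(s) with zero voxels in the mask: ",
         paste(which(cnt == 0L), collapse = ", "))
  out <- rowsum(series, group = nodeLab, reorder = TRUE) / cnt
  dimnames(out) <- NULL
  out
}

#' @rdname extractNodeSeries
#' @export
setMethod("extractNodeSeries", signature(x = "SyntheticCohort",
                                         parc = "ParcellationScheme"),
  function(x, parc, ...) {
    if (!identical(dim(labelArray(parc)), dim(labelArray(x@atlas))))
      stop("parcellation grid does not match the cohort's atlas grid")
    nodeLab <- as.integer(labelArray(parc)[x@voxelIndex])
    if (any(nodeLab == 0L))
      stop("cohort foreground voxels fall outside the parcellation")
    lapply(subjectSeries(x), node_means, nodeLab = nodeLab,
           nNodes = achievedN(parc))
  })

#' @rdname extractNodeSeries
#' @param voxelIndex linear indices into the parcellation grid for the rows
#'   of `x` (matrix method only).
#' @export
setMethod("extractNodeSeries", signature(x = "matrix",
                                         parc = "ParcellationScheme"),
  function(x, parc, voxelIndex, ...) {
    nodeLab <- as.integer(labelArray(parc)[voxelIndex])
    if (any(nodeLab == 0L))
      stop("some voxels fall outside the parcellation")
    node_means(x, nodeLab, achievedN(parc))
  })

#' Remove nuisance signal from node time series
#'
#' Replaces every node series by its least-squares residual against an
#' intercept plus the supplied regressors (motion parameters, tissue
#' signals).  Residuals are orthogonal to the regressors; regressing a
#' second time is a no-op.
#'
#' @param nodeSeries node x time numeric matrix.
#' @param regressors time x q numeric matrix, full column rank.
#' @return Residual node x time matrix.
#' @export
nuisanceRegress <- function(nodeSeries, regressors) {
  nodeSeries <- as.matrix(nodeSeries)
  X <- cbind(intercept = 1, as.matrix(regressors))
  if (nrow(X) != ncol(nodeSeries))
    stop("regressor rows must equal the series length")
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    stop("rank-deficient regressors; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  t(qr.resid(qr_x, t(nodeSeries)))
}

#' Pearson correlation matrix of node series
#'
#' @param nodeSeries node x time matrix (typically nuisance-regressed).
#' @return Symmetric node x node matrix of Pearson r; the diagonal is 1 by
#'   convention and is ignored by [thresholdBySparsity()].
#' @export
correlationMatrix <- function(nodeSeries) {
  nodeSeries <- as.matrix(nodeSeries)
  if (ncol(nodeSeries) < 3L)
    stop("at least 3 timepoints are required")
  v <- apply(nodeSeries, 1L, stats::var)
  if (any(v <= 0 | !is.finite(v)))
    stop("zero-variance node series: ",
         paste(which(v <= 0 | !is.finite(v)), collapse = ", "))
  stats::cor(t(nodeSeries))
}

#' Binarize a correlation matrix at a proportional sparsity threshold
#'
#' Sparsity S is the ratio of retained edges to the `n(n-1)/2` possible
#' edges.  The `round(S * n(n-1)/2)` strongest entries of the upper triangle
#' become edges.  By default edges are ranked by signed r (largest positive
#' correlations first); set `ranking = "absolute"` to rank by `|r|`.  Ties
#' are broken lexicographically by (i, j) for determinism.
#'
#' @param corr node x node correlation matrix.
#' @param S target sparsity in `(0, 1]`.
#' @param ranking `"signed"` (default) or `"absolute"`.
#' @return 0/1 adjacency matrix with attributes `sparsity` (achieved) and
#'   `edges`.
#' @export
thresholdBySparsity <- function(corr, S, ranking = c("signed", "absolute")) {
  ranking <- match.arg(ranking)
  stopifnot(S > 0, S <= 1)
  n <- nrow(corr)
  ut <- which(upper.tri(corr), arr.ind = TRUE)
  m <- nrow(ut)
  E <- as.integer(round(S * m))
  adj <- matrix(0L, n, n)
  if (E < 1L) {
    warning("sparsity ", S, " keeps no edges; returning an empty graph")
  } else {
    val <- corr[ut]
    if (ranking == "absolute") val <- abs(val)
    keep <- order(-val, ut[, 1L], ut[, 2L])[seq_len(E)]
    adj[ut[keep, , drop = FALSE]] <- 1L
    adj[ut[keep, c(2L, 1L), drop = FALSE]] <- 1L
  }
  structure(adj, sparsity = sum(adj) / 2 / m, edges = as.integer(sum(adj) / 2))
}

#' Sparsity threshold grid
#'
#' Default grid `{0.08, 0.13, 0.18, 0.23, 0.28}`: a 5% step through the
#' (8%, 32%) sparsity window commonly used for binary functional networks.
#'
#' @param from,to,by grid start, end and step (fractions).
#' @return Strictly increasing numeric vector of sparsities.
#' @export
sparsityGrid <- function(from = 0.08, to = 0.28, by = 0.05) {
  if (by <= 0) stop("step must be positive")
  if (to < from) stop("'to' must be >= 'from'")
  if (from <= 0 || to > 1) stop("sparsities must lie in (0, 1]")
  seq(from, to, by = by)
}
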