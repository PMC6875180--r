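# Nodal graph metrics on binary networks and their AUC integration across
# the sparsity grid.  Shortest-path machinery is delegated to igraph.

adj_graph <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj != 0, mode = "undirected",
                                      diag = FALSE)
}

#' Nodal degree
#'
#' @param adj 0/1 symmetric adjacency matrix.
#' @return Integer vector of row sums (edges incident to each node).
#' @export
nodeDegree <- function(adj) {
  as.integer(rowSums(adj != 0))
}

#' Nodal betweenness centrality
#'
#' Fraction of all-pairs shortest paths passing through each node.  With
#' `normalized = TRUE` (default) values are divided by `(n-1)(n-2)/2`, the
#' number of node pairs excluding the node itself, keeping scales comparable
#' across parcellations.  Pairs in different components contribute 0.
#'
#' @param adj 0/1 symmetric adjacency matrix.
#' @param normalized divide by `(n-1)(n-2)/2`?
#' @return Numeric vector of betweenness values.
#' @export
nodeBetweenness <- function(adj, normalized = TRUE) {
  n <- nrow(adj)
  b <- igraph::betweenness(adj_graph(adj), directed = FALSE)
  if (normalized && n > 2) b <- b / ((n - 1) * (n - 2) / 2)
  unname(b)
}

#' Nodal efficiency
#'
#' Mean inverse shortest-path distance from each node to all others:
#' `E(i) = (1/(n-1)) * sum_j 1/d(i, j)`, with `1/Inf = 0` for unreachable
#' nodes.  Equals 1 in a complete graph and 0 for an isolated node.
#'
#' @param adj 0/1 symmetric adjacency matrix.
#' @return Numeric vector in `[0, 1]`.
#' @export
nodalEfficiency <- function(adj) {
  n <- nrow(adj)
  if (n < 2) return(rep(0, n))
  d <- igraph::distances(adj_graph(adj))
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  unname(rowSums(inv) / (n - 1))
}

#' Nodal metric curves across the sparsity grid
#'
#' Thresholds the correlation matrix at every sparsity in `grid` and
#' evaluates the three nodal metrics on each binary network.
#'
#' @param corr node x node correlation matrix.
#' @param grid strictly increasing sparsity values (see [sparsityGrid()]).
#' @param ranking edge ranking rule, see [thresholdBySparsity()].
#' @return Named list of node x sparsity matrices: `degree`, `betweenness`,
#'   `efficiency`; an attribute `grid` stores the sparsity values.
#' @export
metricCurves <- function(corr, grid = sparsityGrid(),
                         ranking = c("signed", "absolute")) {
  ranking <- match.arg(ranking)
  if (!length(grid)) stop("empty sparsity grid")
  n <- nrow(corr)
  deg <- bet <- eff <- matrix(NA_real_, n, length(grid))
  for (g in seq_along(grid)) {
    adj <- thresholdBySparsity(corr, grid[g], ranking)
    deg[, g] <- nodeDegree(adj)
    bet[, g] <- nodeBetweenness(adj)
    eff[, g] <- nodalEfficiency(adj)
  }
  structure(list(degree = deg, betweenness = bet, efficiency = eff),
            grid = grid)
}

#' Trapezoidal area under a metric-sparsity curve
#'
#' Collapses a per-node metric curve over the sparsity grid into one scalar
#' per node by trapezoidal integration on the raw grid (no renormalisation
#' by the grid range).
#'
#' @param values numeric vector (one curve) or node x sparsity matrix.
#' @param grid strictly increasing sparsity values, length >= 2.
#' @return Scalar, or one value per row of `values`.
#' @export
aucIntegrate <- function(values, grid) {
  if (length(grid) < 2L)
    stop("AUC needs at least 2 grid points; choose an explicit aggregation ",
         "for single-threshold analyses")
  if (is.unsorted(grid, strictly = TRUE))
    stop("grid must be strictly increasing")
  if (is.matrix(values)) {
    stopifnot(ncol(values) == length(grid))
    dx <- diff(grid)
    mid <- (values[, -1L, drop = FALSE] + values[, -ncol(values),
                                                 drop = FALSE]) / 2
    as.numeric(mid %*% dx)
  } else {
    stopifnot(length(values) == length(grid))
    sum(diff(grid) * (head(values, -1L) + tail(values, -1L)) / 2)
  }
}

#' Build the subjects-by-features AUC table for a cohort
#'
#' Runs the full per-subject network pipeline -- node-mean extraction,
#' nuisance regression, Pearson correlation, sparsity thresholding, nodal
#' metrics and AUC integration -- and assembles the result into an
#' [AUCFeatureTable-class] with `3 * achievedN` features (degree,
#' betweenness, efficiency per node).  Subjects whose network construction
#' fails are excluded with a message.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param parc a [ParcellationScheme-class] on the cohort's atlas grid.
#' @param grid sparsity grid ([sparsityGrid()]).
#' @param ranking edge ranking rule, see [thresholdBySparsity()].
#' @return An [AUCFeatureTable-class] (features x subjects).
#' @examples
#' atlas <- generateAtlas(c(10, 10, 8), 4, seed = 1)
#' coh <- generateCohort(atlas, cohortSpec(3, 3, 40))
#' parc <- subdivideAtlas(atlas, N = 8, seed = 2)
#' tab <- buildFeatureTable(coh, parc)
#' dim(tab)  # 24 features x 6 subjects
#' @export
buildFeatureTable <- function(cohort, parc, grid = sparsityGrid(),
                              ranking = c("signed", "absolute")) {
  ranking <- match.arg(ranking)
  nodeSeries <- extractNodeSeries(cohort, parc)
  n <- length(nodeSeries)
  N <- achievedN(parc)
  feats <- matrix(NA_real_, 3L * N, n)
  ok <- rep(TRUE, n)
  for (s in seq_len(n)) {
    res <- tryCatch({
      resid <- nuisanceRegress(nodeSeries[[s]], nuisanceRegressors(cohort)[[s]])
      crv <- metricCurves(correlationMatrix(resid), grid, ranking)
      c(aucIntegrate(crv$degree, grid),
        aucIntegrate(crv$betweenness, grid),
        aucIntegrate(crv$efficiency, grid))
    }, error = function(e) {
      message("excluding subject ", s, ": ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) ok[s] <- FALSE else feats[, s] <- res
  }
  cen <- nodeCentroids(parc)
  meta <- S4Vectors::DataFrame(
    metric = rep(c("degree", "betweenness", "efficiency"), each = N),
    node = rep.int(seq_len(N), 3L),
    parent = rep.int(as.integer(parentOf(parc)), 3L),
    cx = rep.int(cen[, 1L], 3L), cy = rep.int(cen[, 2L], 3L),
    cz = rep.int(cen[, 3L], 3L)
  )
  rownames(feats) <- paste0(meta$metric, "_n",
                            formatC(meta$node, width = 4, flag = "0"))
  colnames(feats) <- paste0("subj", formatC(seq_len(n), width = 3, flag = "0"))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(auc = feats[, ok, drop = FALSE]),
    rowData = meta,
    colData = S4Vectors::DataFrame(group = groupLabels(cohort)[ok],
                                   row.names = colnames(feats)[ok]),
    metadata = list(grid = grid, targetN = targetN(parc), achievedN = N,
                    ranking = ranking)
  )
  new("AUCFeatureTable", se)
}
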