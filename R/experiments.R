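# Orchestration of the multiscale experiment: for each target node count,
# run parcellation -> networks -> AUC features -> screening ->
# classification -> mRMR, and collect a per-scale report.

#' Run the full scale sweep
#'
#' For every target node count in `Ns`, subdivides the cohort's atlas,
#' builds the AUC feature table, screens features (KS + BH-FDR), classifies
#' with the FDR-selected subset under repeated stratified k-fold CV, and
#' (optionally) evaluates features with the mRMR machinery: the P-vs-MID
#' regression, the accuracy-vs-feature-count sweep, mean pairwise
#' redundancy of the selected subset and its regression on inter-node
#' distance.  Fully deterministic given `seed`.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param Ns integer vector of target node counts.
#' @param seed RNG seed governing parcellation and every CV draw.
#' @param q FDR level for discriminative-feature selection.
#' @param grid sparsity grid.
#' @param cvK,cvRepeats CV folds and repeats for the headline accuracy.
#' @param sweepStep,sweepRepeats step and repeats for the
#'   accuracy-vs-feature-count curve.
#' @param runSweep,runMrmr toggles for the expensive stages.
#' @param maxSweepFeatures optional cap on the sweep length.
#' @param alpha discretization width for the mRMR stage.
#' @return A list of class `ScaleSweepReport`: element `scales` holds one
#'   sub-list per N (achieved N, feature counts, screen, CV rates, curves,
#'   regressions), element `config` echoes the settings.
#' @export
runScaleSweep <- function(cohort, Ns, seed = 1, q = 0.05,
                          grid = sparsityGrid(), cvK = 10, cvRepeats = 100,
                          sweepStep = 3, sweepRepeats = 5,
                          runSweep = TRUE, runMrmr = TRUE,
                          maxSweepFeatures = NULL, alpha = 1) {
  stopifnot(is(cohort, "SyntheticCohort"))
  scales <- vector("list", length(Ns))
  names(scales) <- paste0("N", Ns)
  for (i in seq_along(Ns)) {
    N <- Ns[i]
    parc <- subdivideAtlas(cohort@atlas, N, seed = substream_seed(seed, N))
    tab <- buildFeatureTable(cohort, parc, grid = grid)
    screen <- screenFeatures(tab, q = q)
    sel <- selectFeatures(screen, "fdr", q)
    counts <- vapply(c("degree", "efficiency", "betweenness"), function(m)
      sum(screen$metric[sel] == m), 0L)
    cv <- if (length(sel) >= 1L)
      repeatedKFold(tab, features = sel, k = cvK, repeats = cvRepeats,
                    seed = substream_seed(seed, N + 1L)) else NULL
    res <- list(
      targetN = N, achievedN = achievedN(parc),
      totalFeatures = nrow(tab),
      nSelected = length(sel),
      selectedByMetric = counts,
      screen = screen,
      cv = cv
    )
    if (runSweep) {
      res$accuracyCurve <- accuracyVsFeatureCount(
        tab, screen, step = sweepStep, repeats = sweepRepeats, k = cvK,
        maxFeatures = maxSweepFeatures, seed = substream_seed(seed, N + 2L))
    }
    if (runMrmr) {
      disc <- discretizeFeatures(tab, alpha = alpha)
      grp <- SummarizedExperiment::colData(tab)$group
      pfm <- perFeatureMid(disc, grp)
      res$pMidRegression <- pMidRegression(screen, pfm$score)
      if (length(sel) >= 2L) {
        red <- redundancyMatrix(disc, sel)
        dmat <- featurePairDistances(tab, sel)
        res$meanRedundancy <- mean(red[upper.tri(red)], na.rm = TRUE)
        res$redundancyDistance <- tryCatch(
          redundancyDistanceRegression(red, dmat),
          error = function(e) NULL)
      }
    }
    scales[[i]] <- res
  }
  structure(list(
    scales = scales,
    config = list(Ns = Ns, seed = seed, q = q, grid = grid, cvK = cvK,
                  cvRepeats = cvRepeats, sweepStep = sweepStep,
                  sweepRepeats = sweepRepeats, alpha = alpha)
  ), class = "ScaleSweepReport")
}

#' @export
print.ScaleSweepReport <- function(x, ...) {
  cat("ScaleSweepReport over N =", paste(x$config$Ns, collapse = ", "), "\n")
  for (s in x$scales) {
    cat(sprintf(
      "  N=%d (achieved %d): %d features, %d discriminative%s\n",
      s$targetN, s$achievedN, s$totalFeatures, s$nSelected,
      if (!is.null(s$cv)) sprintf(", accuracy %.3f", s$cv$accuracy) else ""))
  }
  invisible(x)
}

#' Compare scales at a fixed number of features
#'
#' For every scale in the report and every requested feature count, takes
#' the top-count features by raw P and re-runs repeated CV.  A cell is
#' omitted (`NA`) when a scale's discriminative-feature pool is smaller
#' than the requested count.
#'
#' @param tables named list of [AUCFeatureTable-class] objects, one per
#'   scale.
#' @param screens matching list of [screenFeatures()] results.
#' @param counts feature counts to compare at.
#' @param poolMode `"fdr"` limits the per-scale pool to FDR-selected
#'   features (cells exceeding the pool are omitted); `"all"` draws from
#'   the full P ranking.
#' @param q FDR level used when `poolMode = "fdr"`.
#' @param k,repeats,seed CV settings.
#' @return Matrix of accuracies (scales x counts) with `NA` for omitted
#'   cells.
#' @export
sameFeatureCountComparison <- function(tables, screens, counts,
                                       poolMode = c("fdr", "all"), q = 0.05,
                                       k = 10, repeats = 20, seed = 1) {
  poolMode <- match.arg(poolMode)
  if (!length(counts)) stop("counts must be nonempty")
  stopifnot(length(tables) == length(screens))
  acc <- matrix(NA_real_, length(tables), length(counts),
                dimnames = list(names(tables), counts))
  for (i in seq_along(tables)) {
    pool <- if (poolMode == "fdr")
      selectFeatures(screens[[i]], "fdr", q)
    else selectFeatures(screens[[i]], "top_k", nrow(screens[[i]]))
    for (j in seq_along(counts)) {
      if (counts[j] > length(pool)) next  # omitted cell
      fs <- pool[seq_len(counts[j])]
      cv <- repeatedKFold(tables[[i]], features = fs, k = k,
                          repeats = repeats,
                          seed = substream_seed(seed, i * 1000L + j))
      acc[i, j] <- cv$accuracy
    }
  }
  acc
}
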