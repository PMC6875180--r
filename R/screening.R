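# Feature screening: two-sample Kolmogorov-Smirnov tests with
# Benjamini-Hochberg FDR control, and the three selection modes.

#' Two-sample Kolmogorov-Smirnov test
#'
#' Statistic `D = sup |ECDF_x - ECDF_y|` with, by default, the asymptotic
#' two-sample P value (the usual choice at case-control sample sizes of a
#' few dozen); set `exact = TRUE` for the exact small-sample distribution.
#' Ties are handled natively by the ECDFs.
#'
#' @param x,y numeric samples, each of size >= 2.
#' @param exact use the exact null distribution?
#' @return List with elements `statistic` (D) and `p.value`.
#' @export
ksTwoSample <- function(x, y, exact = FALSE) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each sample needs at least 2 observations")
  res <- suppressWarnings(stats::ks.test(x, y, exact = exact))
  list(statistic = unname(res$statistic), p.value = unname(res$p.value))
}

#' Benjamini-Hochberg step-up FDR selection
#'
#' Standard step-up rule: with sorted P values `p_(1) <= ... <= p_(m)`,
#' reject all `i <= max{i : p_(i) <= i * q / m}`.  Adjusted P values are the
#' cumulative minimum of `m * p_(i) / i`, equivalent to
#' `p.adjust(method = "BH")`.
#'
#' @param pvals numeric P values in `[0, 1]`.
#' @param q FDR level in `(0, 1)`.
#' @return List with `padj` (adjusted P values, original order) and
#'   `selected` (logical mask, `padj <= q`).
#' @export
bhFdr <- function(pvals, q = 0.05) {
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("P values must lie in [0, 1]")
  padj <- stats::p.adjust(pvals, method = "BH")
  list(padj = padj, selected = !is.na(padj) & padj <= q)
}

#' Screen AUC features for group differences
#'
#' Applies the two-sample KS test to every feature (patients vs controls)
#' and corrects with BH-FDR.  The correction family is all features of the
#' parcellation pooled (default) or each metric separately.
#'
#' @param table an [AUCFeatureTable-class].
#' @param q FDR level.
#' @param family `"pooled"` (one BH family across all features) or
#'   `"per_metric"` (BH within each metric's features).
#' @param exact exact KS P values? See [ksTwoSample()].
#' @return A [S4Vectors::DataFrame] with one row per feature: `feature`,
#'   `metric`, `node`, `D`, `p`, `padj`, `rank` (by raw P ascending, ties by
#'   feature index) and `selected` (`padj <= q`).
#' @export
screenFeatures <- function(table, q = 0.05, family = c("pooled", "per_metric"),
                           exact = FALSE) {
  stopifnot(is(table, "AUCFeatureTable"))
  family <- match.arg(family)
  x <- SummarizedExperiment::assay(table, "auc")
  grp <- SummarizedExperiment::colData(table)$group
  pat <- grp == "patient"
  ks <- apply(x, 1L, function(f) {
    r <- ksTwoSample(f[pat], f[!pat], exact = exact)
    c(r$statistic, r$p.value)
  })
  D <- ks[1L, ]; p <- ks[2L, ]
  rd <- SummarizedExperiment::rowData(table)
  if (family == "pooled") {
    fdr <- bhFdr(p, q)
    padj <- fdr$padj; sel <- fdr$selected
  } else {
    padj <- numeric(length(p)); sel <- logical(length(p))
    for (m in unique(rd$metric)) {
      i <- rd$metric == m
      fdr <- bhFdr(p[i], q)
      padj[i] <- fdr$padj; sel[i] <- fdr$selected
    }
  }
  rk <- integer(length(p))
  rk[order(p, seq_along(p))] <- seq_along(p)
  S4Vectors::DataFrame(
    feature = seq_along(p), metric = rd$metric, node = rd$node,
    D = unname(D), p = unname(p), padj = padj, rank = rk, selected = sel,
    row.names = rownames(table)
  )
}

#' Select features from a screen
#'
#' @param screen result of [screenFeatures()].
#' @param mode `"fdr"` (all features with adjusted P `<=` `param`),
#'   `"top_k"` (the `param` smallest raw P values) or `"p_threshold"` (raw
#'   P `<` `param`).  Ties are always resolved by feature index.
#' @param param FDR level, k, or raw-P threshold according to `mode`.
#' @return Integer vector of selected feature indices, ordered by ascending
#'   raw P (ties by index).
#' @export
selectFeatures <- function(screen, mode = c("fdr", "top_k", "p_threshold"),
                           param = 0.05) {
  mode <- match.arg(mode)
  ord <- order(screen$p, screen$feature)
  sel <- switch(mode,
    fdr = screen$feature[ord][screen$padj[ord] <= param],
    p_threshold = screen$feature[ord][screen$p[ord] < param],
    top_k = {
      k <- param
      if (k > nrow(screen)) {
        warning("k = ", k, " exceeds the ", nrow(screen),
                " available features; clipping")
        k <- nrow(screen)
      }
      screen$feature[ord][seq_len(k)]
    })
  as.integer(sel)
}
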