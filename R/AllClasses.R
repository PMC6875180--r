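#' @import methods
NULL

# ---------------------------------------------------------------------------
# LabelAtlas
# ---------------------------------------------------------------------------

#' Labelled brain atlas volume
#'
#' A `LabelAtlas` holds a 3D integer label grid assigning every voxel to a
#' parent region (0 = background) together with the physical voxel spacing in
#' mm.  It is the parent scheme that [subdivideAtlas()] refines into
#' finer-grained parcellations.
#'
#' @slot labels 3D integer array; region id per voxel, 0 for background.
#' @slot spacing numeric length-3; voxel size per axis in mm.
#' @slot regionIds sorted integer vector of the parent region ids present.
#'
#' @seealso [generateAtlas()], [subdivideAtlas()], [volumeFractions()]
#' @export
setClass("LabelAtlas",
  representation(
    labels = "array",
    spacing = "numeric",
    regionIds = "integer"
  )
)

setValidity("LabelAtlas", function(object) {
  msg <- character()
  d <- dim(object@labels)
  if (length(d) != 3L || any(d < 1L))
    msg <- c(msg, "labels must be a 3D array with all dimensions >= 1")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive finite values (mm)")
  lab <- unique(as.integer(object@labels))
  lab <- sort(lab[lab != 0L])
  if (!identical(lab, object@regionIds))
    msg <- c(msg, "regionIds must equal the sorted nonzero labels present")
  if (length(lab) == 0L)
    msg <- c(msg, "atlas has no foreground voxels")
  if (length(msg)) msg else TRUE
})

#' Construct a LabelAtlas
#'
#' @param labels 3D integer array of region ids (0 = background).
#' @param spacing numeric length-3 voxel size in mm (default 3 mm isotropic,
#'   the usual normalised rs-fMRI resolution).
#' @return A [LabelAtlas-class] object.
#' @export
LabelAtlas <- function(labels, spacing = c(3, 3, 3)) {
  storage.mode(labels) <- "integer"
  ids <- sort(unique(as.integer(labels)))
  ids <- ids[ids != 0L]
  new("LabelAtlas", labels = labels, spacing = as.numeric(spacing),
      regionIds = ids)
}

# ---------------------------------------------------------------------------
# ParcellationScheme
# ---------------------------------------------------------------------------

#' Refined parcellation of a labelled atlas
#'
#' A `ParcellationScheme` maps every foreground voxel to a subregion (network
#' node).  Subregions never cross parent-region boundaries; each one records
#' its parent id and mass centroid in mm.
#'
#' @slot labels 3D integer array of subregion ids (0 = background).
#' @slot parentOf integer vector, parent region id per subregion; names are
#'   subregion ids.
#' @slot targetN integer, requested node count N.
#' @slot achievedN integer, actual node count (may deviate from N because
#'   per-region subregion counts are rounded).
#' @slot centroids achievedN x 3 numeric matrix of subregion mass centres in
#'   mm; rownames are subregion ids.
#' @slot spacing voxel size in mm, copied from the parent atlas.
#' @slot seed integer RNG seed used to draw the growing seeds.
#'
#' @seealso [subdivideAtlas()], [centroidDistances()]
#' @export
setClass("ParcellationScheme",
  representation(
    labels = "array",
    parentOf = "integer",
    targetN = "integer",
    achievedN = "integer",
    centroids = "matrix",
    spacing = "numeric",
    seed = "integer"
  )
)

setValidity("ParcellationScheme", function(object) {
  msg <- character()
  lab <- unique(as.integer(object@labels))
  lab <- sort(lab[lab != 0L])
  if (length(lab) != object@achievedN)
    msg <- c(msg, "achievedN must equal the number of distinct nonzero labels")
  if (length(object@parentOf) != object@achievedN)
    msg <- c(msg, "parentOf must have one entry per subregion")
  if (nrow(object@centroids) != object@achievedN ||
      ncol(object@centroids) != 3L)
    msg <- c(msg, "centroids must be achievedN x 3")
  if (any(!is.finite(object@centroids)))
    msg <- c(msg, "centroids must be finite")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# SyntheticCohort
# ---------------------------------------------------------------------------

#' Synthetic two-group voxel time-series cohort
#'
#' Holds per-subject voxel-by-time matrices (foreground voxels only), binary
#' group labels, the per-subject nuisance regressors that were mixed into the
#' signal, and the ground-truth set of affected parent regions.
#'
#' @slot series list of voxel x time numeric matrices, one per subject; rows
#'   are aligned with `voxelIndex`.
#' @slot group factor with levels `control`, `patient`; one label per subject.
#' @slot nuisance list of time x regressor matrices, one per subject.
#' @slot truth integer ids of the parent regions carrying the planted effect.
#' @slot atlas the [LabelAtlas-class] the cohort was simulated on.
#' @slot voxelIndex linear indices (into the atlas grid) of the foreground
#'   voxels, in row order of each series matrix.
#'
#' @seealso [generateCohort()], [extractNodeSeries()]
#' @export
setClass("SyntheticCohort",
  representation(
    series = "list",
    group = "factor",
    nuisance = "list",
    truth = "integer",
    atlas = "LabelAtlas",
    voxelIndex = "integer"
  )
)

setValidity("SyntheticCohort", function(object) {
  msg <- character()
  n <- length(object@series)
  if (length(object@group) != n)
    msg <- c(msg, "one group label per subject required")
  if (length(object@nuisance) != n)
    msg <- c(msg, "one nuisance matrix per subject required")
  if (!identical(levels(object@group), c("control", "patient")))
    msg <- c(msg, "group levels must be control, patient")
  if (n > 0L) {
    tt <- vapply(object@series, ncol, 0L)
    if (length(unique(tt)) != 1L)
      msg <- c(msg, "all subjects must share the same number of timepoints")
    nr <- vapply(object@nuisance, nrow, 0L)
    if (any(nr != tt[1L]))
      msg <- c(msg, "nuisance rows must equal the number of timepoints")
    nv <- vapply(object@series, nrow, 0L)
    if (any(nv != length(object@voxelIndex)))
      msg <- c(msg, "series rows must match voxelIndex length")
  }
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# AUCFeatureTable
# ---------------------------------------------------------------------------

#' Subjects-by-features table of sparsity-AUC graph metrics
#'
#' An `AUCFeatureTable` extends [SummarizedExperiment::SummarizedExperiment]
#' with rows = features (one per metric/node combination) and columns =
#' subjects.  The single assay `"auc"` holds the trapezoidal area under each
#' nodal metric's sparsity curve.  `rowData` records the metric name, node id,
#' parent region and node centroid; `colData` records the group label.
#'
#' @seealso [buildFeatureTable()], [screenFeatures()]
#' @export
setClass("AUCFeatureTable", contains = "SummarizedExperiment")

setValidity("AUCFeatureTable", function(object) {
  msg <- character()
  if (!"auc" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'auc' is required")
  rd <- SummarizedExperiment::rowData(object)
  need <- c("metric", "node", "parent", "cx", "cy", "cz")
  if (!all(need %in% colnames(rd)))
    msg <- c(msg, paste("rowData must contain:", paste(need, collapse = ", ")))
  if (!"group" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain 'group'")
  if (length(msg)) msg else TRUE
})
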