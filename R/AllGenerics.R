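#' @rdname LabelAtlas-class
#' @param object,x a package object.
#' @export
setGeneric("labelArray", function(x) standardGeneric("labelArray"))

#' @rdname LabelAtlas-class
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname LabelAtlas-class
#' @export
setGeneric("regionIds", function(x) standardGeneric("regionIds"))

#' @rdname ParcellationScheme-class
#' @export
setGeneric("parentOf", function(x) standardGeneric("parentOf"))

#' @rdname ParcellationScheme-class
#' @export
setGeneric("targetN", function(x) standardGeneric("targetN"))

#' @rdname ParcellationScheme-class
#' @export
setGeneric("achievedN", function(x) standardGeneric("achievedN"))

#' @rdname ParcellationScheme-class
#' @export
setGeneric("nodeCentroids", function(x) standardGeneric("nodeCentroids"))

#' @rdname SyntheticCohort-class
#' @export
setGeneric("subjectSeries", function(x) standardGeneric("subjectSeries"))

#' @rdname SyntheticCohort-class
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))

#' @rdname SyntheticCohort-class
#' @export
setGeneric("nuisanceRegressors", function(x) standardGeneric("nuisanceRegressors"))

#' @rdname SyntheticCohort-class
#' @export
setGeneric("truthRegions", function(x) standardGeneric("truthRegions"))

#' Extract node-mean time series
#'
#' @param x a [SyntheticCohort-class] or a voxel x time matrix.
#' @param parc a [ParcellationScheme-class] aligned with the voxel grid.
#' @param ... further arguments passed to methods.
#' @return For a cohort, a list of node x time matrices (one per subject);
#'   for a single matrix, one node x time matrix.
#' @export
setGeneric("extractNodeSeries", function(x, parc, ...)
  standardGeneric("extractNodeSeries"))
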