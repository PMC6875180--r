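# Accessors and show() methods for the core classes.

#' @rdname LabelAtlas-class
#' @export
setMethod("labelArray", "LabelAtlas", function(x) x@labels)

#' @rdname ParcellationScheme-class
#' @export
setMethod("labelArray", "ParcellationScheme", function(x) x@labels)

#' @rdname LabelAtlas-class
#' @export
setMethod("voxelSpacing", "LabelAtlas", function(x) x@spacing)

#' @rdname ParcellationScheme-class
#' @export
setMethod("voxelSpacing", "ParcellationScheme", function(x) x@spacing)

#' @rdname LabelAtlas-class
#' @export
setMethod("regionIds", "LabelAtlas", function(x) x@regionIds)

#' @rdname ParcellationScheme-class
#' @export
setMethod("parentOf", "ParcellationScheme", function(x) x@parentOf)

#' @rdname ParcellationScheme-class
#' @export
setMethod("targetN", "ParcellationScheme", function(x) x@targetN)

#' @rdname ParcellationScheme-class
#' @export
setMethod("achievedN", "ParcellationScheme", function(x) x@achievedN)

#' @rdname ParcellationScheme-class
#' @export
setMethod("nodeCentroids", "ParcellationScheme", function(x) x@centroids)

#' @rdname SyntheticCohort-class
#' @export
setMethod("subjectSeries", "SyntheticCohort", function(x) x@series)

#' @rdname SyntheticCohort-class
#' @export
setMethod("groupLabels", "SyntheticCohort", function(x) x@group)

#' @rdname SyntheticCohort-class
#' @export
setMethod("nuisanceRegressors", "SyntheticCohort", function(x) x@nuisance)

#' @rdname SyntheticCohort-class
#' @export
setMethod("truthRegions", "SyntheticCohort", function(x) x@truth)

setMethod("show", "LabelAtlas", function(object) {
  d <- dim(object@labels)
  nfg <- sum(object@labels != 0L)
  cat("LabelAtlas:", paste(d, collapse = " x "), "grid,",
      length(object@regionIds), "regions,", nfg, "foreground voxels\n")
  cat("  spacing (mm):", paste(object@spacing, collapse = " x "), "\n")
})

setMethod("show", "ParcellationScheme", function(object) {
  cat("ParcellationScheme: target N =", object@targetN,
      "| achieved N =", object@achievedN, "\n")
  cat("  parents:", length(unique(object@parentOf)),
      "| seed:", object@seed, "\n")
})

setMethod("show", "SyntheticCohort", function(object) {
  tab <- table(object@group)
  cat("SyntheticCohort:", length(object@series), "subjects (",
      tab[["patient"]], "patients /", tab[["control"]], "controls ),",
      if (length(object@series)) ncol(object@series[[1L]]) else 0L,
      "timepoints\n")
  cat("  foreground voxels:", length(object@voxelIndex),
      "| planted-effect regions:",
      if (length(object@truth)) paste(object@truth, collapse = ", ")
      else "none", "\n")
})
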