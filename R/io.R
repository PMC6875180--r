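# NIfTI / TSV / JSON input-output for the pipeline's artifacts.

#' Read and write label volumes as NIfTI-1
#'
#' Atlases and parcellations are stored as integer label volumes; the voxel
#' spacing travels in the NIfTI pixdim.
#'
#' @param atlas a [LabelAtlas-class].
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `writeAtlasNifti` returns `path` invisibly; `readAtlasNifti`
#'   returns a [LabelAtlas-class].
#' @export
writeAtlasNifti <- function(atlas, path) {
  im <- RNifti::asNifti(labelArray(atlas))
  RNifti::pixdim(im) <- voxelSpacing(atlas)
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' @rdname writeAtlasNifti
#' @export
readAtlasNifti <- function(path) {
  im <- RNifti::readNifti(path)
  LabelAtlas(array(as.integer(round(im)), dim = dim(im)),
             spacing = RNifti::pixdim(im)[1:3])
}

#' @rdname writeAtlasNifti
#' @param parc a [ParcellationScheme-class].
#' @export
writeParcellationNifti <- function(parc, path) {
  im <- RNifti::asNifti(labelArray(parc))
  RNifti::pixdim(im) <- voxelSpacing(parc)
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' Write the node table of a parcellation
#'
#' TSV with one row per subregion: id, parent region, voxel count and
#' centroid x/y/z in mm.
#'
#' @param parc a [ParcellationScheme-class].
#' @param path output TSV path.
#' @export
writeNodeTable <- function(parc, path) {
  lab <- labelArray(parc)
  cnt <- tabulate(lab[lab != 0L], nbins = achievedN(parc))
  cen <- nodeCentroids(parc)
  df <- data.frame(node = seq_len(achievedN(parc)),
                   parent = as.integer(parentOf(parc)), voxels = cnt,
                   x_mm = cen[, 1L], y_mm = cen[, 2L], z_mm = cen[, 3L])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic cohort to disk
#'
#' One 4D NIfTI per subject (series scattered back into the atlas grid),
#' a TSV manifest (subject id, group) and one TSV of nuisance regressors
#' per subject.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
writeCohortNifti <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dimg <- dim(labelArray(cohort@atlas))
  n <- length(subjectSeries(cohort))
  ids <- sprintf("sub-%03d", seq_len(n))
  for (s in seq_len(n)) {
    y <- subjectSeries(cohort)[[s]]
    vol <- array(0, dim = c(dimg, ncol(y)))
    step <- prod(dimg)
    for (t in seq_len(ncol(y)))
      vol[cohort@voxelIndex + (t - 1L) * step] <- y[, t]
    im <- RNifti::asNifti(vol)
    RNifti::pixdim(im) <- c(voxelSpacing(cohort@atlas), 2)  # TR 2 s
    RNifti::writeNifti(im, file.path(dir, paste0(ids[s], "_bold.nii.gz")))
    utils::write.table(
      as.data.frame(nuisanceRegressors(cohort)[[s]]),
      file.path(dir, paste0(ids[s], "_nuisance.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- file.path(dir, "participants.tsv")
  utils::write.table(
    data.frame(subject = ids, group = as.character(groupLabels(cohort))),
    manifest, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Write / read an AUC feature table as TSV + JSON sidecar
#'
#' The TSV holds the subjects x features matrix (subjects in rows, group in
#' the first column); the JSON sidecar carries the feature metadata (metric,
#' node, parent, centroid) and the sparsity grid, so the table round-trips.
#'
#' @param table an [AUCFeatureTable-class].
#' @param path TSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `writeFeatureTable` returns `path` invisibly;
#'   `readFeatureTable` an [AUCFeatureTable-class].
#' @export
writeFeatureTable <- function(table, path) {
  x <- t(SummarizedExperiment::assay(table, "auc"))
  df <- cbind(
    data.frame(subject = rownames(x),
               group = as.character(SummarizedExperiment::colData(table)$group)),
    as.data.frame(x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  rd <- as.data.frame(SummarizedExperiment::rowData(table))
  side <- list(features = rd,
               grid = S4Vectors::metadata(table)$grid,
               targetN = S4Vectors::metadata(table)$targetN,
               achievedN = S4Vectors::metadata(table)$achievedN,
               ranking = S4Vectors::metadata(table)$ranking)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  mat <- t(as.matrix(df[, -(1:2), drop = FALSE]))
  colnames(mat) <- df$subject
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(auc = mat),
    rowData = S4Vectors::DataFrame(side$features),
    colData = S4Vectors::DataFrame(
      group = factor(df$group, levels = c("control", "patient")),
      row.names = df$subject),
    metadata = list(grid = side$grid, targetN = side$targetN,
                    achievedN = side$achievedN, ranking = side$ranking)
  )
  new("AUCFeatureTable", se)
}
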