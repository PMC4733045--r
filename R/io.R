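#' Write / read a pattern dataset as TSV + JSON sidecar
#'
#' The trials x voxels matrix is stored as tab-separated text (one row per
#' trial, columns `v1..vN`), the trial metadata alongside it as
#' `<stem>_meta.tsv`, and voxel geometry / ROI labels in a JSON sidecar
#' `<stem>.json` -- all plain text, so datasets round-trip without binary
#' formats.
#'
#' @param dataset a [pattern_dataset()].
#' @param stem output path stem (files `<stem>.tsv`, `<stem>_meta.tsv`,
#'   `<stem>.json`).
#' @return `read_patterns` returns the [pattern_dataset()].
#' @export
write_patterns <- function(dataset, stem) {
  mat <- dataset$matrix
  colnames(mat) <- paste0("v", seq_len(ncol(mat)))
  utils::write.table(mat, paste0(stem, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(dataset$meta, paste0(stem, "_meta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "n/a")
  sidecar <- list(n_trials = nrow(mat), n_voxels = ncol(mat))
  if (!is.null(dataset$voxel_coords))
    sidecar$voxel_coords <- unname(as.matrix(dataset$voxel_coords))
  if (!is.null(dataset$roi_labels))
    sidecar$roi_labels <- as.integer(dataset$roi_labels)
  jsonlite::write_json(sidecar, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' @rdname write_patterns
#' @export
read_patterns <- function(stem) {
  mat <- as.matrix(utils::read.table(paste0(stem, ".tsv"), header = TRUE,
                                     sep = "\t"))
  meta <- utils::read.table(paste0(stem, "_meta.tsv"), header = TRUE,
                            sep = "\t", na.strings = "n/a",
                            stringsAsFactors = FALSE)
  sidecar <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  voxel_coords <- if (!is.null(sidecar$voxel_coords))
    as.matrix(sidecar$voxel_coords) else NULL
  roi_labels <- sidecar$roi_labels
  pattern_dataset(mat, meta, voxel_coords, roi_labels)
}

#' Write ground-truth generator parameters as JSON
#'
#' Records the synthetic truth (templates summary and generator
#' parameters) next to a simulated dataset, so analyses can be audited
#' against what was injected.
#'
#' @param templates a [make_city_templates()] object.
#' @param path output `.json` path.
#' @param extra optional named list of additional parameters to record.
#' @export
write_truth_json <- function(templates, path, extra = list()) {
  truth <- c(list(n_voxels = templates$n_voxels,
                  separation = templates$separation,
                  attraction_mix = templates$attraction_mix,
                  seed = templates$seed,
                  template_correlations =
                    round(stats::cor(templates$templates), 6)),
             extra)
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a per-centre searchlight accuracy map as NIfTI
#'
#' @param result a `searchlight_result`.
#' @param geometry geometry from [make_default_geometry()].
#' @param path output `.nii` / `.nii.gz` path.
#' @export
write_accuracy_nifti <- function(result, geometry, path) {
  vol <- array(NA_real_, dim = geometry$dims)
  in_mask <- which(geometry$mask > 0)
  vol[in_mask[result$centers]] <- result$accuracy
  RNifti::writeNifti(RNifti::asNifti(vol), path)
  invisible(path)
}
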