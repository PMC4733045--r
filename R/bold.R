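#' Simulate BOLD time series for the retrieval runs
#'
#' Forward model at the time-series level: every voxel's signal in a run is
#' the superposition, over that run's trials, of the trial's amplitude at
#' that voxel times the trial regressor (a boxcar of the trial duration
#' convolved with the HRF), plus white Gaussian noise. This is the exact
#' generative counterpart of the single-trial GLM in
#' [estimate_single_trial_betas()], so noise-free simulations are recovered
#' to numerical precision.
#'
#' @param events event table from [make_event_table()] (columns `onset`,
#'   `duration`, `run` plus metadata).
#' @param amplitudes per-trial voxel amplitudes: a trials x voxels matrix
#'   aligned to `events` rows, a [pattern_dataset()] (its matrix is used),
#'   or a [make_city_templates()] object (each trial gets its city's
#'   template).
#' @param hrf an [hrf_kernel()]; its sampling interval sets the microtime
#'   grid on which regressors are built.
#' @param tr repetition time in seconds (default 3).
#' @param noise_sd white-noise standard deviation (default 0).
#' @param seed seed for the noise.
#' @param pad_scans scans appended after the last trial offset (default 10)
#'   so late haemodynamic responses are not truncated.
#' @return list with one element per run: a `n_scans x n_voxels` matrix of
#'   BOLD samples (scan times `0, tr, 2 tr, ...`).
#' @export
simulate_bold_runs <- function(events, amplitudes, hrf, tr = 3,
                               noise_sd = 0, seed = 1L, pad_scans = 10L) {
  if (nrow(events) == 0L) stop("empty event table")
  if (noise_sd < 0) stop("`noise_sd` must be nonnegative")
  if (!inherits(hrf, "hrf_kernel")) stop("`hrf` must be an `hrf_kernel`")
  amp <- amplitude_matrix_(amplitudes, events)
  nv <- ncol(amp)

  runs <- sort(unique(events$run))
  out <- with_seed_(seed, {
    lapply(runs, function(r) {
      idx <- which(events$run == r)
      ev <- events[idx, , drop = FALSE]
      if (is.unsorted(ev$onset, strictly = TRUE))
        stop("onsets must be strictly increasing within a run")
      n_scans <- ceiling(max(ev$onset + ev$duration) / tr) + pad_scans
      X <- trial_regressors_(ev$onset, ev$duration, hrf, n_scans, tr)
      sig <- X %*% amp[idx, , drop = FALSE]
      if (noise_sd > 0)
        sig <- sig + matrix(stats::rnorm(length(sig), sd = noise_sd),
                            nrow(sig), ncol(sig))
      sig
    })
  })
  names(out) <- paste0("run", runs)
  out
}

# Resolve the three accepted amplitude representations to a matrix.
amplitude_matrix_ <- function(amplitudes, events) {
  if (inherits(amplitudes, "pattern_dataset")) {
    amp <- amplitudes$matrix
  } else if (inherits(amplitudes, "city_templates")) {
    amp <- t(amplitudes$templates[, events$city, drop = FALSE])
  } else {
    amp <- as.matrix(amplitudes)
  }
  if (nrow(amp) != nrow(events))
    stop("amplitude rows must align with event rows")
  amp
}

# Build the n_scans x n_trials matrix of convolved trial regressors:
# boxcar(onset, duration) (x) hrf, constructed on the HRF's microtime grid
# and sampled at the scan times.
trial_regressors_ <- function(onsets, durations, hrf, n_scans, tr) {
  dt <- hrf$dt
  run_end <- (n_scans - 1) * tr
  if (any(onsets > run_end))
    stop("event onset lies beyond the end of the run")
  grid <- seq(0, run_end, by = dt)
  scan_idx <- round(seq(0, n_scans - 1) * tr / dt) + 1L
  X <- matrix(0, n_scans, length(onsets))
  h <- hrf$samples
  for (i in seq_along(onsets)) {
    box <- as.numeric(grid >= onsets[i] & grid < onsets[i] + durations[i])
    conv <- stats::convolve(box, rev(h), type = "open")[seq_along(grid)]
    X[, i] <- conv[scan_idx]
  }
  X
}

#' Write / read 4D BOLD volumes as NIfTI-1
#'
#' Embeds a scans x voxels run matrix into the package's grid geometry and
#' writes it as a 4D NIfTI-1 volume (and back). Voxels are laid out in
#' array order following `geometry$voxel_coords`.
#'
#' @param run scans x voxels matrix, as produced by [simulate_bold_runs()].
#' @param geometry geometry from [make_default_geometry()].
#' @param path output `.nii` / `.nii.gz` path.
#' @param tr repetition time stored in the header, seconds.
#' @return `read_bold_nifti` returns the scans x voxels matrix.
#' @export
write_bold_nifti <- function(run, geometry, path, tr = 3) {
  dims <- geometry$dims
  n_scans <- nrow(run)
  arr <- array(0, dim = c(dims, n_scans))
  flat <- array(t(run), dim = c(dims, n_scans))
  arr[] <- flat
  img <- RNifti::asNifti(arr, pixdim = c(1.6, 1.6, 2, tr))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_bold_nifti
#' @export
read_bold_nifti <- function(path, geometry) {
  arr <- RNifti::readNifti(path)
  dims <- dim(arr)
  if (!all(dims[1:3] == geometry$dims))
    stop("volume grid does not match the supplied geometry")
  n_scans <- if (length(dims) == 4L) dims[4] else 1L
  t(matrix(arr, prod(dims[1:3]), n_scans))
}

#' Write / read an integer label mask as NIfTI-1
#' @param mask 3D integer array (e.g. `geometry$mask`).
#' @param path file path.
#' @return `read_mask_nifti` returns the integer 3D array.
#' @export
write_mask_nifti <- function(mask, path) {
  RNifti::writeNifti(RNifti::asNifti(mask, datatype = "int16"), path)
  invisible(path)
}

#' @rdname write_mask_nifti
#' @export
read_mask_nifti <- function(path) {
  arr <- RNifti::readNifti(path)
  array(as.integer(round(arr)), dim = dim(arr))
}
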