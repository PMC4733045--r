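#' Finite impulse response (FIR) design matrix
#'
#' One indicator column per trial per post-onset scan bin: column
#' `(trial t, bin j)` carries a 1 at the scan `j` steps after the trial's
#' onset scan (onsets are mapped to the nearest scan). Columns are ordered
#' trial-major (trial 1 bins 1..n_bins, then trial 2, ...). Bins that would
#' fall beyond the end of the run are simply left empty.
#'
#' The FIR model estimates the haemodynamic response shape without
#' assuming a canonical form: regressing a run on this design yields, per
#' trial and voxel, one coefficient per scan of the `n_bins * tr` seconds
#' following stimulus onset.
#'
#' Estimating one response per trial is only identifiable when the design
#' leaves enough scans per regressor (sparse or well-jittered onsets); for
#' the dense retrieval blocks, `per_trial = FALSE` collapses all trials of
#' the run onto one shared set of `n_bins` columns, estimating the run's
#' average response shape -- the form used for empirical HRF extraction.
#'
#' @param events single-run event table (rows with `onset`; seconds).
#' @param n_scans number of scans in the run.
#' @param tr repetition time, seconds.
#' @param n_bins number of post-onset bins (default 10, i.e. a 30 s
#'   response window at `tr = 3`).
#' @param per_trial one set of bins per trial (default) or one shared set
#'   for the whole run.
#' @return numeric `n_scans x (n_trials * n_bins)` matrix with column
#'   names `trial<t>_bin<j>` (or `n_scans x n_bins`, columns `bin<j>`,
#'   when `per_trial = FALSE`).
#' @export
build_fir_design <- function(events, n_scans, tr, n_bins = 10L,
                             per_trial = TRUE) {
  if (n_bins < 1) stop("`n_bins` must be >= 1")
  if (n_bins > n_scans) stop("`n_bins` exceeds the run length")
  onset_scan <- round(events$onset / tr)
  if (any(onset_scan >= n_scans) || any(onset_scan < 0))
    stop("event onset lies outside the run")
  nt <- nrow(events)
  if (per_trial) {
    X <- matrix(0, n_scans, nt * n_bins)
    for (t in seq_len(nt)) {
      for (j in seq_len(n_bins)) {
        s <- onset_scan[t] + j - 1L
        if (s < n_scans) X[s + 1L, (t - 1L) * n_bins + j] <- 1
      }
    }
    colnames(X) <- paste0("trial", rep(seq_len(nt), each = n_bins),
                          "_bin", rep(seq_len(n_bins), nt))
  } else {
    X <- matrix(0, n_scans, n_bins)
    for (t in seq_len(nt)) {
      for (j in seq_len(n_bins)) {
        s <- onset_scan[t] + j - 1L
        if (s < n_scans) X[s + 1L, j] <- X[s + 1L, j] + 1
      }
    }
    colnames(X) <- paste0("bin", seq_len(n_bins))
  }
  X
}

#' Fit a per-trial FIR model to one run
#'
#' Ordinary least squares of the run data on the FIR design (plus an
#' intercept), reshaped to a trials x voxels x bins coefficient array.
#'
#' @param run scans x voxels data matrix.
#' @param events single-run event table.
#' @param tr repetition time, seconds.
#' @param n_bins post-onset bins (default 10).
#' @param per_trial per-trial bins (default) or one shared response per
#'   run; see [build_fir_design()].
#' @return object of class `fir_estimate`: list with `coef` (array
#'   trials x voxels x bins; first extent 1 when `per_trial = FALSE`),
#'   `n_bins`, `tr`.
#' @export
fit_fir <- function(run, events, tr, n_bins = 10L, per_trial = TRUE) {
  run <- as.matrix(run)
  X <- build_fir_design(events, nrow(run), tr, n_bins, per_trial)
  fit <- stats::lm.fit(cbind(X, intercept = 1), run)
  cf <- fit$coefficients[seq_len(ncol(X)), , drop = FALSE]
  cf[is.na(cf)] <- 0
  nt <- if (per_trial) nrow(events) else 1L
  nv <- ncol(run)
  # columns are trial-major: (trial, bin) x voxel -> trials x voxels x bins
  arr <- aperm(array(cf, dim = c(n_bins, nt, nv)), c(2L, 3L, 1L))
  structure(list(coef = arr, n_bins = as.integer(n_bins), tr = tr),
            class = "fir_estimate")
}

#' Average FIR time courses into HRF profiles
#'
#' Collapses a `fir_estimate` over trials, returning one `n_bins`-long
#' response profile per voxel -- the rows fed to
#' [extract_empirical_hrf()]. Profiles from several runs or subjects can
#' be stacked with `rbind()`.
#'
#' @param fir a `fir_estimate` from [fit_fir()].
#' @return voxels x bins matrix.
#' @export
fir_profiles <- function(fir) {
  if (!inherits(fir, "fir_estimate")) stop("`fir` must be a `fir_estimate`")
  apply(fir$coef, c(2L, 3L), mean)
}

#' Single-trial beta estimation (per-trial GLM)
#'
#' Builds one regressor per trial -- a boxcar of the trial's duration
#' convolved with the supplied HRF on its microtime grid, sampled at the
#' scan times -- and fits all trials of a run in a single joint ordinary
#' least squares model (plus intercept). The resulting trials x voxels
#' beta matrix, with metadata carried over from the event table, is the
#' input to every multivariate analysis in this package.
#'
#' @param runs list of scans x voxels run matrices (as from
#'   [simulate_bold_runs()]), or a single matrix for a one-run dataset.
#' @param events event table covering all runs (`run` column matches the
#'   list order).
#' @param hrf an [hrf_kernel()], typically resampled to microtime
#'   resolution with [resample_hrf()].
#' @param tr repetition time, seconds.
#' @param voxel_coords,roi_labels optional geometry to attach to the
#'   result.
#' @return a [pattern_dataset()] of per-trial betas.
#' @export
estimate_single_trial_betas <- function(runs, events, hrf, tr = 3,
                                        voxel_coords = NULL,
                                        roi_labels = NULL) {
  if (!inherits(hrf, "hrf_kernel")) stop("`hrf` must be an `hrf_kernel`")
  if (is.matrix(runs)) runs <- list(runs)
  run_ids <- sort(unique(events$run))
  if (length(runs) != length(run_ids))
    stop(sprintf("%d runs supplied but events reference %d run ids",
                 length(runs), length(run_ids)))

  betas <- vector("list", length(run_ids))
  for (k in seq_along(run_ids)) {
    idx <- which(events$run == run_ids[k])
    ev <- events[idx, , drop = FALSE]
    run <- as.matrix(runs[[k]])
    X <- trial_regressors_(ev$onset, ev$duration, hrf, nrow(run), tr)
    D <- cbind(X, intercept = 1)
    qrd <- qr(D)
    if (qrd$rank < ncol(D)) {
      dropped <- qrd$pivot[(qrd$rank + 1L):ncol(D)]
      bad <- dropped[dropped <= ncol(X)]
      stop(sprintf("singular design in run %s: trial regressors {%s} are collinear",
                   run_ids[k], paste(idx[bad], collapse = ", ")))
    }
    cf <- qr.coef(qrd, run)
    betas[[k]] <- cf[seq_len(ncol(X)), , drop = FALSE]
  }
  mat <- do.call(rbind, betas)
  order_idx <- unlist(lapply(run_ids, function(r) which(events$run == r)))
  meta <- events[order_idx, setdiff(names(events), c("onset", "duration")),
                 drop = FALSE]
  meta$run <- NULL
  rownames(mat) <- NULL
  rownames(meta) <- NULL
  for (col in c("attracted_to")) {
    if (is.null(meta[[col]])) meta[[col]] <- NA_integer_
  }
  pattern_dataset(mat, meta, voxel_coords, roi_labels)
}
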