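#' Haemodynamic response kernels
#'
#' A sampled haemodynamic response function (HRF): the impulse response
#' linking a neural event to the BOLD signal, stored with its sampling
#' interval and (for empirically extracted kernels) the fraction of
#' variance its back-projection explains in the profiles it was derived
#' from.
#'
#' @param samples numeric vector of kernel samples (length >= 2).
#' @param dt sampling interval in seconds.
#' @param variance_explained fraction in `[0, 1]` or `NA`.
#' @return object of class `hrf_kernel`.
#' @export
hrf_kernel <- function(samples, dt, variance_explained = NA_real_) {
  if (length(samples) < 2L) stop("an HRF kernel needs at least 2 samples")
  if (!is.finite(dt) || dt <= 0) stop("`dt` must be a positive interval")
  if (!is.na(variance_explained) &&
      (variance_explained < 0 || variance_explained > 1))
    stop("`variance_explained` must lie in [0, 1]")
  structure(list(samples = as.numeric(samples), dt = dt,
                 variance_explained = variance_explained),
            class = "hrf_kernel")
}

#' @export
print.hrf_kernel <- function(x, ...) {
  cat(sprintf("hrf_kernel: %d samples at dt = %g s (%.1f s support)\n",
              length(x$samples), x$dt, (length(x$samples) - 1) * x$dt))
  if (!is.na(x$variance_explained))
    cat(sprintf("  variance explained: %.1f%%\n",
                100 * x$variance_explained))
  invisible(x)
}

#' Canonical double-gamma HRF
#'
#' The standard two-gamma haemodynamic response (peak around 5 s, undershoot
#' around 15 s): `h(t) = dgamma(t, 6, 1) - dgamma(t, 16, 1) / 6`, scaled to
#' unit peak.
#'
#' @param dt sampling interval in seconds.
#' @param duration kernel support in seconds (default 30).
#' @return an [hrf_kernel()].
#' @export
canonical_hrf <- function(dt, duration = 30) {
  t <- seq(0, duration, by = dt)
  h <- double_gamma_(t)
  hrf_kernel(h / max(h), dt)
}

# Closed-form double-gamma evaluation, shared with tests as an oracle.
double_gamma_ <- function(t) {
  stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
}

#' Extract an empirical HRF from FIR profiles
#'
#' Decomposes a matrix of per-voxel (or per-voxel-per-block) FIR time
#' courses into temporal components and returns the single component whose
#' back-projection explains the most variance, sign-aligned so its peak is
#' positive. This mirrors the practice of estimating one subject-specific
#' response shape from finite-impulse-response deconvolutions rather than
#' assuming a canonical form.
#'
#' Two decompositions are available. `"infomax_ica"` runs logistic infomax
#' independent component analysis (natural-gradient Bell-Sejnowski update)
#' on the PCA-whitened profile scores; because ICA components are not
#' variance-ordered, the returned component is explicitly the one with the
#' largest back-projected variance. `"first_pc"` takes the first singular
#' vector of the (uncentred) profile matrix, which is also the natural
#' cross-check for the ICA route when one shape dominates.
#'
#' @param profiles numeric matrix, profiles x time bins (>= 2 rows).
#' @param method `"infomax_ica"` (default) or `"first_pc"`.
#' @param dt sampling interval of the FIR bins in seconds (default 3, one
#'   repetition time per bin).
#' @param n_components number of components for ICA (default:
#'   `min(nrow, ncol, 8)`, reduced to the numerical rank).
#' @param seed seed for the ICA row permutations (the algorithm is
#'   otherwise deterministic from an identity initialisation).
#' @return an [hrf_kernel()] with `variance_explained` filled in.
#' @export
extract_empirical_hrf <- function(profiles,
                                  method = c("infomax_ica", "first_pc"),
                                  dt = 3, n_components = NULL, seed = 1L) {
  method <- match.arg(method)
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 2L)
    stop("need at least 2 FIR profiles to extract an HRF")
  if (any(!is.finite(profiles))) stop("profiles contain non-finite values")
  total_var <- sum(profiles^2)
  if (total_var == 0) stop("profiles are constant zero; no HRF to extract")

  sv <- svd(profiles)
  tol <- max(dim(profiles)) * .Machine$double.eps * sv$d[1]
  rank <- sum(sv$d > tol)
  if (rank == 0L) stop("profile matrix is rank deficient")

  if (method == "first_pc" || rank == 1L) {
    kern <- sv$v[, 1L] * sv$d[1L]
    ve <- sv$d[1L]^2 / sum(sv$d^2)
  } else {
    k <- if (is.null(n_components)) min(dim(profiles), 8L) else n_components
    k <- min(k, rank)
    # Whitened scores (unit variance per retained direction) and the
    # temporal basis that reconstructs the profiles from them.
    scores <- sv$u[, seq_len(k), drop = FALSE]
    basis <- diag(sv$d[seq_len(k)], k) %*% t(sv$v[, seq_len(k), drop = FALSE])
    W <- infomax_unmix_(scores, seed = seed)
    S <- scores %*% t(W)                  # profiles x components
    M <- solve(t(W)) %*% basis            # components x bins
    ve_all <- (colSums(S^2) * rowSums(M^2)) / total_var
    j <- which.max(ve_all)
    kern <- M[j, ]
    ve <- min(ve_all[j], 1)
  }
  if (kern[which.max(abs(kern))] < 0) kern <- -kern
  hrf_kernel(kern / max(kern), dt, variance_explained = ve)
}

# Logistic infomax ICA unmixing matrix (Bell-Sejnowski with the natural
# gradient), on whitened data; rows are observations. Identity start,
# seeded row shuffles, annealed learning rate.
infomax_unmix_ <- function(z, seed = 1L, max_iter = 400L, tol = 1e-7) {
  n <- nrow(z); k <- ncol(z)
  W <- diag(k)
  lr <- 0.01 / log(k + 2)
  with_seed_(seed, {
    for (it in seq_len(max_iter)) {
      perm <- sample.int(n)
      u <- z[perm, , drop = FALSE] %*% t(W)
      g <- 1 / (1 + exp(-u))
      grad <- (diag(k) + crossprod(1 - 2 * g, u) / n) %*% W
      W_new <- W + lr * grad
      delta <- max(abs(W_new - W))
      W <- W_new
      if (delta < tol) break
      if (it %% 100L == 0L) lr <- lr * 0.7
    }
  })
  W
}

#' Resample an HRF kernel by cubic spline interpolation
#'
#' Upsamples a kernel to a finer microtime grid (default 16 bins per scan,
#' the conventional regressor-building resolution). The cubic spline
#' interpolant passes through the original samples exactly.
#'
#' @param hrf an [hrf_kernel()] with at least 4 samples.
#' @param bins_per_scan upsampling factor (new `dt = dt / bins_per_scan`).
#' @return an [hrf_kernel()] at the finer sampling interval.
#' @export
resample_hrf <- function(hrf, bins_per_scan = 16L) {
  if (!inherits(hrf, "hrf_kernel")) stop("`hrf` must be an `hrf_kernel`")
  if (length(hrf$samples) < 4L)
    stop("cubic interpolation needs at least 4 samples")
  if (bins_per_scan < 1) stop("`bins_per_scan` must be >= 1")
  n <- length(hrf$samples)
  x <- (seq_len(n) - 1) * hrf$dt
  dt_out <- hrf$dt / bins_per_scan
  xout <- seq(0, x[n], by = dt_out)
  y <- stats::spline(x, hrf$samples, xout = xout, method = "fmm")$y
  hrf_kernel(y, dt_out, variance_explained = hrf$variance_explained)
}
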