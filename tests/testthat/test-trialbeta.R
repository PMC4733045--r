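# Single-trial estimation: FIR design, empirical HRF, spline resampling,
# per-trial GLM betas.

test_that("FIR design places indicator columns at post-onset scans", {
  ev <- data.frame(onset = 15, duration = 3)   # scan 5 at tr = 3
  X <- build_fir_design(ev, n_scans = 30, tr = 3, n_bins = 10)
  expect_equal(dim(X), c(30, 10))
  for (j in 1:10) {
    expect_equal(sum(X[, j]), 1)
    expect_equal(which(X[, j] == 1), 5 + j)    # scan 5+j-1, 1-based row
  }
  # two non-overlapping events: block structure, columns disjoint
  ev2 <- data.frame(onset = c(0, 60), duration = 3)
  X2 <- build_fir_design(ev2, n_scans = 40, tr = 3, n_bins = 10)
  expect_equal(X2[1:10, 1:10], diag(10), ignore_attr = TRUE)
  expect_equal(X2[21:30, 11:20], diag(10), ignore_attr = TRUE)
  expect_true(all(crossprod(X2[, 1:10], X2[, 11:20]) == 0))

  expect_error(build_fir_design(data.frame(onset = 200, duration = 3),
                                30, 3), "outside")
  expect_error(build_fir_design(ev, 5, 3, n_bins = 10), "exceeds")
})

test_that("FIR least squares recovers an injected HRF exactly", {
  h <- canonical_hrf(3)
  h$samples <- h$samples[1:10]                 # 10-bin ground truth at TR
  ev <- data.frame(onset = seq(6, by = 33, length.out = 6), duration = 3,
                   run = 1)
  amp <- matrix(runif(6 * 4, 0.5, 2), 6, 4)
  run <- simulate_bold_runs(ev, amp, h, tr = 3, noise_sd = 0)[[1]]
  fir <- fit_fir(run, ev, tr = 3, n_bins = 10)
  for (t in 1:6) for (v in 1:4)
    expect_equal(fir$coef[t, v, ], amp[t, v] * h$samples, tolerance = 1e-6,
                 ignore_attr = TRUE)
  prof <- fir_profiles(fir)
  expect_equal(dim(prof), c(4, 10))
})

test_that("shared-bin FIR stays identifiable in dense periodic blocks", {
  # 20 trials at 9 s SOA in a ~70-scan run: per-trial FIR has more
  # regressors than scans, but one shared 10-bin response per run is
  # well-posed and recovers the stimulus-locked response shape
  tpl <- make_city_templates(20, seed = 15)
  ds <- simulate_trial_patterns(tpl, n_trials_per_half = 20, noise_sd = 0,
                                seed = 16)
  ev <- make_event_table(ds$meta, soa = 9, duration = 4, jitter = 3,
                         seed = 17)
  fine <- resample_hrf(canonical_hrf(3), 16)
  runs <- simulate_bold_runs(ev, ds, fine, noise_sd = 0)
  prof <- fir_profiles(fit_fir(runs[[1]], ev[ev$run == 1, ], tr = 3,
                               per_trial = FALSE))
  expect_equal(dim(prof), c(20, 10))
  # oracle: injected HRF convolved with the 4 s boxcar at the scan grid
  box <- as.numeric(seq(0, 30, by = fine$dt) < 4)
  ref <- convolve(box, rev(fine$samples), type = "open")[seq_along(box)]
  ref_tr <- ref[seq(1, length(ref), by = 16)]
  v <- which.max(abs(rowMeans(prof)))
  expect_gt(abs(cor(prof[v, ], ref_tr[1:10])), 0.99)
  # shared design has n_bins columns whose counts sum the trial indicators
  X <- build_fir_design(ev[ev$run == 1, ], 70, 3, per_trial = FALSE)
  Xt <- build_fir_design(ev[ev$run == 1, ], 70, 3, per_trial = TRUE)
  for (j in 1:10)
    expect_equal(X[, j], rowSums(Xt[, seq(j, 200, by = 10)]))
})

test_that("empirical HRF extraction returns the dominant component", {
  shape <- canonical_hrf(3)$samples[1:10]
  # all profiles share one shape: kernel proportional to it, VE ~ 1
  P <- matrix(rep(shape, 30), 30, 10, byrow = TRUE) *
    seq(0.5, 2, length.out = 30)
  for (m in c("infomax_ica", "first_pc")) {
    k <- extract_empirical_hrf(P, m)
    expect_gt(cor(k$samples, shape), 0.9999)
    expect_equal(k$variance_explained, 1, tolerance = 1e-8)
    expect_gt(max(k$samples), 0)             # peak sign-aligned positive
  }

  # 90/10 mixture of orthogonal shapes: A-dominated component wins, and
  # its variance explained beats an eigendecomposition of the B share
  a <- shape / sqrt(sum(shape^2))
  b <- c(1, rep(0, 9)); b <- b - sum(b * a) * a; b <- b / sqrt(sum(b^2))
  P2 <- withr::with_seed(5, rbind(
    matrix(rep(a, 90), 90, 10, byrow = TRUE) * rnorm(90, 1, 0.1),
    matrix(rep(b, 10), 10, 10, byrow = TRUE) * rnorm(10, 1, 0.1)))
  k2 <- extract_empirical_hrf(P2, "infomax_ica")
  expect_gt(abs(cor(k2$samples, a)), 0.99)
  sv <- svd(P2)                               # independent oracle
  expect_equal(k2$variance_explained, sv$d[1]^2 / sum(sv$d^2),
               tolerance = 0.05)

  expect_error(extract_empirical_hrf(matrix(shape, 1, 10)), "2 FIR|2 prof")
  expect_error(extract_empirical_hrf(matrix(0, 5, 10)), "constant")
})

test_that("spline resampling is exact on the original grid", {
  # linear ramp: interpolation returns the same ramp at fine resolution
  ramp <- hrf_kernel(seq(0, 1, length.out = 6), dt = 3)
  up <- resample_hrf(ramp, 4)
  expect_equal(up$dt, 0.75)
  expect_equal(up$samples, seq(0, 1, length.out = length(up$samples)),
               tolerance = 1e-10)
  # resample then decimate at the original grid recovers the input
  hc <- canonical_hrf(3)
  up16 <- resample_hrf(hc, 16)
  expect_equal(up16$samples[seq(1, length(up16$samples), by = 16)],
               hc$samples, tolerance = 1e-10)
  expect_error(resample_hrf(hrf_kernel(c(0, 1, 0), 1)), "4 samples")
})

test_that("spline fidelity depends on the base sampling interval", {
  # closed-form double-gamma oracle at the fine grid
  fine_t <- seq(0, 30, by = 1 / 16)
  direct <- remapkit:::double_gamma_(fine_t)
  peak <- max(abs(direct))
  # adequately sampled (1 s): interpolation error under 2% of peak
  h1 <- hrf_kernel(remapkit:::double_gamma_(seq(0, 30, by = 1)), dt = 1)
  up1 <- resample_hrf(h1, 16)
  expect_lt(max(abs(up1$samples - direct)) / peak, 0.02)
  # undersampled (3 s, one sample per scan): the initial rise cannot be
  # represented and the error is an order of magnitude larger -- frozen
  # from the closed-form oracle so the behaviour is documented
  fine3 <- seq(0, 30, by = 3 / 16)
  direct3 <- remapkit:::double_gamma_(fine3)
  h3 <- hrf_kernel(remapkit:::double_gamma_(seq(0, 30, by = 3)), dt = 3)
  up3 <- resample_hrf(h3, 16)
  err3 <- max(abs(up3$samples - direct3)) / max(abs(direct3))
  expect_equal(err3, 0.177, tolerance = 0.01)
})

test_that("single-trial betas recover overlapping trial patterns", {
  tpl <- make_city_templates(30, seed = 11)
  meta <- make_trial_meta(5)
  meta <- meta[meta$city %in% 1:2 & meta$block_half == "A", ]  # 10 trials
  ev <- cbind(data.frame(onset = 6 + (seq_len(nrow(meta)) - 1) * 9,
                         duration = 4, run = 1), meta)
  amp <- t(tpl$templates[, meta$city])
  hrf <- resample_hrf(canonical_hrf(3), 16)
  run <- simulate_bold_runs(ev, amp, hrf, tr = 3, noise_sd = 0)[[1]]
  est <- estimate_single_trial_betas(run, ev, hrf, tr = 3)
  expect_lt(max(abs(est$matrix - amp)), 1e-6)
  expect_identical(est$meta$city, meta$city)

  # all-zero data: all betas zero
  est0 <- estimate_single_trial_betas(matrix(0, nrow(run), 30), ev, hrf)
  expect_true(all(est0$matrix == 0))

  # identical onsets make the design singular, reported per trial
  ev_bad <- ev; ev_bad$onset[2] <- ev_bad$onset[1]
  expect_error(estimate_single_trial_betas(run, ev_bad, hrf),
               "collinear")
})

test_that("beta estimation is equivariant to voxel permutation and scale", {
  tpl <- make_city_templates(20, seed = 12)
  meta <- make_trial_meta(3)
  meta <- meta[meta$city == 1, ]
  ev <- cbind(data.frame(onset = 6 + (seq_len(nrow(meta)) - 1) * 12,
                         duration = 4, run = 1), meta)
  amp <- matrix(rnorm(nrow(ev) * 20), nrow(ev), 20)
  hrf <- resample_hrf(canonical_hrf(3), 16)
  run <- simulate_bold_runs(ev, amp, hrf, noise_sd = 0)[[1]]
  est <- estimate_single_trial_betas(run, ev, hrf)
  perm <- sample(20)
  est_p <- estimate_single_trial_betas(run[, perm], ev, hrf)
  expect_equal(est_p$matrix, est$matrix[, perm], tolerance = 1e-10)
  est_s <- estimate_single_trial_betas(3.5 * run, ev, hrf)
  expect_equal(est_s$matrix, 3.5 * est$matrix, tolerance = 1e-8)
})

test_that("estimation pipeline preserves decoding information", {
  # decode ground-truth patterns vs patterns re-estimated from simulated
  # BOLD: with low noise the two routes agree
  tpl <- make_city_templates(40, seed = 13)
  ds <- simulate_trial_patterns(tpl, n_trials_per_half = 4, noise_sd = 0.1,
                                seed = 14)
  ev <- make_event_table(ds$meta)
  hrf <- resample_hrf(canonical_hrf(3), 16)
  runs <- simulate_bold_runs(ev, ds, hrf, noise_sd = 0, seed = 15)
  est <- estimate_single_trial_betas(runs, ev, hrf)
  acc_true <- classify_patterns(ds)$overall_accuracy
  acc_est <- classify_patterns(est)$overall_accuracy
  expect_equal(acc_est, acc_true, tolerance = 0.1)
  expect_lt(max(abs(est$matrix - ds$matrix)), 1e-6)
})

test_that("hrf kernel constructor validates inputs", {
  expect_error(hrf_kernel(1, 1), "2 samples")
  expect_error(hrf_kernel(c(0, 1), 0), "dt")
  expect_error(hrf_kernel(c(0, 1), 1, variance_explained = 1.5), "0, 1")
})
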