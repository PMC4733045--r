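# Pattern similarity: Fisher z, trial matching, MPS, remapping index,
# interference analysis, univariate control.

test_that("fisher_z is atanh with boundary errors", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5493, tolerance = 1e-4)
  expect_equal(fisher_z(0.5), atanh(0.5), tolerance = 1e-15)
  expect_true(is.finite(fisher_z(0.999999)) && fisher_z(0.999999) > 7)
  expect_error(fisher_z(1), "< 1")
  expect_error(fisher_z(-1), "< 1")
})

test_that("triad matching pairs the same stimulus across halves", {
  ds <- quick_dataset(n_trials_per_half = 20)
  # within city, 20 shared triads, all correct: 20 pairs
  p <- match_trial_pairs(ds, 1, 1, "triad_matched")
  expect_equal(nrow(p), 20)
  expect_true(all(ds$meta$triad_id[p$i] == ds$meta$triad_id[p$j]))
  expect_true(all(ds$meta$block_half[p$i] != ds$meta$block_half[p$j]))
  # between cities, cross-half both ways: 40 pairs
  p13 <- match_trial_pairs(ds, 1, 3, "triad_matched")
  expect_equal(nrow(p13), 40)
  # all-pairwise between City 4 and City 1 with 18 and 20 correct trials
  ds2 <- ds
  ds2$meta$correct[which(ds2$meta$city == 4)[1:22]] <- FALSE
  p41 <- match_trial_pairs(ds2, 4, 1, "all_pairwise")
  expect_equal(nrow(p41), 18 * 40)     # 18 correct C4 x 40 correct C1
  # a triad present in only one half is excluded
  ds3 <- ds
  drop_triad <- ds3$meta$city == 2 & ds3$meta$block_half == "A" &
    ds3$meta$triad_id == 5
  ds3$meta$correct[drop_triad] <- FALSE
  p22 <- match_trial_pairs(ds3, 2, 2, "triad_matched")
  expect_equal(nrow(p22), 19)
  expect_false(any(ds3$meta$triad_id[p22$i] == 5))
  # no valid pairs: named diagnostic
  ds4 <- ds
  ds4$meta$correct[ds4$meta$city == 2] <- FALSE
  expect_error(match_trial_pairs(ds4, 2, 2, "triad_matched"),
               "city 2")
})

test_that("mps equals atanh of the template correlation when noise-free", {
  # two trials that are exactly two templates with known correlation rho
  rho <- 0.5
  n <- 2000
  base <- withr::with_seed(12, {
    u <- rnorm(n); v <- rnorm(n)
    u <- (u - mean(u)) / sd(u); v <- stats::resid(lm(v ~ u))
    v <- (v - mean(v)) / sd(v)
    cbind(u, rho * u + sqrt(1 - rho^2) * v)
  })
  meta <- make_trial_meta(1)[1:2, ]
  meta$city <- c(1L, 1L); meta$block_half <- c("A", "B")
  meta$triad_id <- c(1L, 1L)
  ds <- pattern_dataset(t(base), meta)
  m <- mps(ds, 1:n, data.frame(i = 1, j = 2))
  expect_equal(m$mean_z, atanh(cor(base[, 1], base[, 2])),
               tolerance = 1e-12)
  expect_equal(m$mean_z, atanh(rho), tolerance = 1e-6)

  # identical patterns: the r = 1 boundary is clipped and counted
  ds_same <- pattern_dataset(rbind(base[, 1], base[, 1]), meta)
  m1 <- mps(ds_same, 1:n, data.frame(i = 1, j = 2))
  expect_equal(m1$n_clipped, 1)
  expect_true(is.finite(m1$mean_z) && m1$mean_z > 7)

  # constant patterns are dropped with a warning
  ds_const <- pattern_dataset(rbind(base[, 1], rep(1, n)), meta)
  expect_warning(expect_error(
    mps(ds_const, 1:n, data.frame(i = 2, j = 2)), "constant"),
    "constant")
})

test_that("orthogonal random patterns have mean similarity near zero", {
  ds <- quick_dataset(n_voxels = 500, noise_sd = 10, seed = 50)
  p <- match_trial_pairs(ds, 1, 2, "triad_matched")
  m <- mps(ds, 1:500, p)
  expect_equal(m$mean_z, 0, tolerance = 0.1)
})

test_that("remapping index equals its defining cell arithmetic", {
  ds <- quick_dataset(n_voxels = 120, noise_sd = 0.2, seed = 51,
                      n_trials_per_half = 10)
  sm <- similarity_matrix(ds, 1:120)
  # identity vs independently recomputed raw-pair arithmetic
  for (city in 1:4) {
    z_within <- naive_mean_z(ds$matrix, 1:120,
                             match_trial_pairs(ds, city, city,
                                               "triad_matched"))
    z_between <- sapply(setdiff(1:4, city), function(b) {
      scheme <- if (city == 4 || b == 4) "all_pairwise" else "triad_matched"
      naive_mean_z(ds$matrix, 1:120,
                   match_trial_pairs(ds, min(city, b), max(city, b), scheme))
    })
    expect_equal(remapping_index(sm, city), z_within - mean(z_between),
                 tolerance = 1e-12)
  }
  # synthetic construction: z_within = mean(z_between) gives exactly 0
  fake <- sm
  fake$z[1, ] <- c(0.2, 0.3, 0.1, 0.2)
  fake$z[1, 1] <- mean(fake$z[1, 2:4])
  expect_equal(remapping_index(fake, 1), 0, tolerance = 1e-15)
  # z_within = atanh(0.5) with zero between-similarity
  fake$z[1, ] <- c(atanh(0.5), 0, 0, 0)
  expect_equal(remapping_index(fake, 1), 0.5493, tolerance = 1e-4)
  fake$z[1, 2] <- NA
  expect_error(remapping_index(fake, 1), "missing")
})

test_that("remapping indices separate cities iff templates are separated", {
  # orthogonal templates: all four indices clearly positive
  ds <- quick_dataset(n_voxels = 300, noise_sd = 0.1, seed = 52,
                      n_trials_per_half = 10)
  idx <- remapping_indices(similarity_matrix(ds, 1:300))
  expect_true(all(idx > 0.2))
  # identical templates across cities: indices near zero
  tpl_same <- make_city_templates(300, separation = 0, seed = 53)
  ds_same <- simulate_trial_patterns(tpl_same, n_trials_per_half = 10,
                                     noise_sd = 0.1, seed = 54)
  idx_same <- remapping_indices(similarity_matrix(ds_same, 1:300))
  expect_true(all(abs(idx_same) < 0.05))
})

test_that("remapping decreases monotonically with template correlation", {
  seps <- c(1, 0.75, 0.5, 0.25, 0)
  mean_idx <- sapply(seq_along(seps), function(k) {
    mean(sapply(1:3, function(s) {
      tpl <- make_city_templates(300, separation = seps[k], seed = s)
      ds <- simulate_trial_patterns(tpl, n_trials_per_half = 8,
                                    noise_sd = 0.1, seed = 60 + s)
      mean(remapping_indices(similarity_matrix(ds, 1:300)))
    }))
  })
  expect_true(all(diff(mean_idx) < 0))
})

test_that("pairing schemes agree on exchangeable between-city data", {
  # mirrors the control analysis: triad-matched vs all-pairwise
  # between-city means agree within sampling error for Cities 1-3
  ds <- quick_dataset(n_voxels = 400, noise_sd = 0.15, seed = 55,
                      n_trials_per_half = 20)
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    z_tm <- mps(ds, 1:400, match_trial_pairs(ds, pair[1], pair[2],
                                             "triad_matched"))$mean_z
    z_ap <- mps(ds, 1:400, match_trial_pairs(ds, pair[1], pair[2],
                                             "all_pairwise"))$mean_z
    expect_equal(z_tm, z_ap, tolerance = 0.05)
  }
})

test_that("within-city matched pairs never share a motor response", {
  ds <- quick_dataset(n_trials_per_half = 20)
  for (city in 1:4) {
    p <- match_trial_pairs(ds, city, city, "triad_matched")
    expect_true(all(ds$meta$response_side[p$i] !=
                      ds$meta$response_side[p$j]))
  }
})

test_that("interference analysis isolates attraction of incorrect trials", {
  tpl <- make_city_templates(400, seed = 56)
  ds <- simulate_trial_patterns(tpl, n_trials_per_half = 20,
                                noise_sd = 0.15, p_attract = 0.5,
                                seed = 57, c3_instability = 0.6,
                                c3_noise_scale = 1.5)
  it <- interference_trial_analysis(ds, 1:400)
  expect_named(it$means, c("inc3_sim", "cor3_sim", "inc3_distinct",
                           "cor3_distinct"))
  expect_gt(it$means["inc3_sim"], it$means["cor3_sim"])
  expect_lt(abs(it$means["inc3_distinct"]), 0.05)
  expect_lt(abs(it$means["cor3_distinct"]), 0.05)

  # null construction: lapses produce incorrect trials without attraction,
  # so no condition differences beyond noise
  ds0 <- simulate_trial_patterns(tpl, n_trials_per_half = 20,
                                 noise_sd = 0.15, p_attract = 0,
                                 lapse = 0.2, seed = 58)
  it0 <- interference_trial_analysis(ds0, 1:400)
  expect_lt(abs(it0$means["inc3_sim"] - it0$means["cor3_sim"]), 0.06)

  # all City 3 trials correct: error naming the empty condition
  ds1 <- quick_dataset(n_trials_per_half = 5)
  expect_error(interference_trial_analysis(ds1, 1:60), "no incorrect")
})

test_that("interference group test compares condition 1 to the others", {
  cm <- withr::with_seed(59, cbind(inc3_sim = rnorm(12, 0.1, 0.02),
                                   cor3_sim = rnorm(12, 0.05, 0.02),
                                   inc3_distinct = rnorm(12, 0, 0.02),
                                   cor3_distinct = rnorm(12, 0, 0.02)))
  g <- interference_group_test(cm)
  expect_equal(nrow(g), 3)
  expect_true(all(g$t > 0))
  expect_true(all(g$p < 0.01))
  expect_equal(g$df, rep(11, 3))
})

test_that("univariate control detects mean shifts but not pattern codes", {
  mk <- function(city_shift = 0, roi_shift = 0, seed) {
    tpl <- make_city_templates(60, seed = seed)
    ds <- simulate_trial_patterns(tpl, n_trials_per_half = 5,
                                  noise_sd = 0.3, seed = seed + 1)
    if (city_shift != 0)
      ds$matrix[ds$meta$city == 2, ] <-
        ds$matrix[ds$meta$city == 2, ] + city_shift
    if (roi_shift != 0) ds$matrix[, 1:30] <- ds$matrix[, 1:30] + roi_shift
    ds
  }
  rois <- list(roiA = 1:30, roiB = 31:60)
  # equal means everywhere: no significant effects
  flat <- lapply(1:6, function(s) mk(seed = 100 + 10 * s))
  a0 <- univariate_control(flat, rois)$anova
  expect_true(all(a0$p > 0.05))
  # one ROI offset uniformly: ROI main effect only
  roi_off <- lapply(1:6, function(s) mk(roi_shift = 0.5, seed = 200 + 10 * s))
  a1 <- univariate_control(roi_off, rois)$anova
  expect_lt(a1$p[a1$effect == "roi"], 0.001)
  expect_gt(a1$p[a1$effect == "city"], 0.05)
  # planted city-specific shift: city effect detected
  city_off <- lapply(1:6, function(s) mk(city_shift = 0.5,
                                         seed = 300 + 10 * s))
  a2 <- univariate_control(city_off, rois)$anova
  expect_lt(a2$p[a2$effect == "city"], 0.01)
})
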