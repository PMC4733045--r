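# Synthetic generator: templates, trial patterns, BOLD forward model, cohort.

test_that("city templates honour the attraction mixture geometry", {
  # independent draws: near-orthogonal unit vectors
  tpl0 <- make_city_templates(100, separation = 1, attraction_mix = 0,
                              seed = 1)
  expect_equal(colSums(tpl0$templates^2), rep(1, 4), tolerance = 1e-12,
               ignore_attr = TRUE)
  off <- cor(tpl0$templates)[upper.tri(diag(4))]
  expect_true(all(abs(off) < 0.35))

  # full attraction: City 3 collapses onto mean(City1, City2)
  tpl1 <- make_city_templates(100, attraction_mix = 1, seed = 1)
  m12 <- (tpl1$templates[, 1] + tpl1$templates[, 2]) / 2
  expect_gt(cor(tpl1$templates[, 3], m12), 0.99)

  # half attraction: closed form lambda / sqrt(lambda^2 + (1-lambda)^2)
  # for a unit-norm mixture of orthogonal components, cross-checked by a
  # brute-force resampling oracle
  lam <- 0.5
  expected <- lam / sqrt(lam^2 + (1 - lam)^2)
  tpl5 <- make_city_templates(10000, attraction_mix = lam, seed = 3)
  m12 <- (tpl5$templates[, 1] + tpl5$templates[, 2]) / 2
  expect_equal(cor(tpl5$templates[, 3], m12), expected, tolerance = 0.03)
  oracle <- withr::with_seed(99, {
    mean(replicate(200, {
      u <- rnorm(500); u <- u / sqrt(sum(u^2))
      a <- rnorm(500); a <- a - sum(a * u) * u; a <- a / sqrt(sum(a^2))
      v <- lam * a + (1 - lam) * u
      cor(v, a)
    }))
  })
  expect_equal(oracle, expected, tolerance = 0.01)
})

test_that("template generation validates inputs and is seed-deterministic", {
  expect_error(make_city_templates(1), "n_voxels")
  expect_error(make_city_templates(100, attraction_mix = 1.2),
               "attraction_mix")
  expect_identical(make_city_templates(50, seed = 7),
                   make_city_templates(50, seed = 7))
  expect_false(identical(make_city_templates(50, seed = 7)$templates,
                         make_city_templates(50, seed = 8)$templates))
})

test_that("noise-free trials reproduce their city template exactly", {
  tpl <- make_city_templates(40, seed = 2)
  ds <- simulate_trial_patterns(tpl, n_trials_per_half = 3, noise_sd = 0,
                                p_attract = 0, seed = 5)
  for (i in seq_len(n_trials(ds)))
    expect_equal(ds$matrix[i, ], tpl$templates[, ds$meta$city[i]],
                 tolerance = 0, ignore_attr = TRUE)
  expect_true(all(ds$meta$correct))
})

test_that("full attraction marks every City 3 trial incorrect", {
  ds <- quick_dataset(p_attract = 1, n_trials_per_half = 10)
  c3 <- ds$meta$city == 3
  expect_true(all(ds$meta$attracted_to[c3] %in% 1:2))
  expect_false(any(ds$meta$correct[c3]))
  expect_true(all(ds$meta$correct[!c3]))
})

test_that("within-city correlation follows the attenuation law", {
  # expected within-city pair correlation 1 / (1 + noise_sd^2 * n_voxels)
  # for unit-norm templates; checked against a Monte-Carlo oracle and for
  # monotone decrease over a noise grid
  nv <- 500
  within_corr <- function(noise_sd, seed) {
    tpl <- make_city_templates(nv, seed = seed)
    ds <- simulate_trial_patterns(tpl, n_trials_per_half = 10,
                                  noise_sd = noise_sd, seed = seed + 1)
    mean(sapply(1:4, function(city) {
      idx <- which(ds$meta$city == city)
      cm <- cor(t(ds$matrix[idx, ]))
      mean(cm[upper.tri(cm)])
    }))
  }
  grid <- c(0.05, 0.1, 0.2, 0.4)
  got <- sapply(seq_along(grid), function(k) within_corr(grid[k], 10 + k))
  expected <- 1 / (1 + grid^2 * nv)
  expect_equal(got, expected, tolerance = 0.05)
  expect_true(all(diff(got) < 0))

  # brute-force oracle at one setting: raw pairs of template + noise draws
  oracle <- withr::with_seed(31, {
    tplv <- make_city_templates(nv, seed = 4)$templates[, 1]
    mean(replicate(2000, {
      x <- tplv + rnorm(nv, sd = 0.1)
      y <- tplv + rnorm(nv, sd = 0.1)
      cor(x, y)
    }))
  })
  expect_equal(oracle, 1 / (1 + 0.01 * nv), tolerance = 0.01)
})

test_that("attracted City 3 trials correlate more with similar cities", {
  tpl <- make_city_templates(300, seed = 6)
  ds <- simulate_trial_patterns(tpl, n_trials_per_half = 20,
                                noise_sd = 0.2, p_attract = 0.5, seed = 7)
  c3 <- which(ds$meta$city == 3)
  sim_cor <- sapply(c3, function(i)
    max(cor(ds$matrix[i, ], tpl$templates[, 1]),
        cor(ds$matrix[i, ], tpl$templates[, 2])))
  attracted <- !ds$meta$correct[c3]
  expect_gt(mean(sim_cor[attracted]), mean(sim_cor[!attracted]))
})

test_that("trial metadata implements the swapped-response design", {
  meta <- make_trial_meta(20)
  expect_equal(nrow(meta), 160)
  expect_equal(unname(table(meta$city)), rep(40L, 4), ignore_attr = TRUE)
  # Cities 1-3 share a triad pool, City 4 is disjoint
  expect_identical(sort(unique(meta$triad_id[meta$city == 1])),
                   sort(unique(meta$triad_id[meta$city == 3])))
  expect_length(intersect(meta$triad_id[meta$city == 4],
                          meta$triad_id[meta$city == 1]), 0)
  # response side for the same triad is swapped between halves
  for (city in 1:4) {
    a <- meta[meta$city == city & meta$block_half == "A", ]
    b <- meta[meta$city == city & meta$block_half == "B", ]
    b <- b[match(a$triad_id, b$triad_id), ]
    expect_true(all(a$response_side != b$response_side))
  }
})

test_that("event tables have strictly increasing onsets within runs", {
  ev <- make_event_table(make_trial_meta(5))
  expect_equal(length(unique(ev$run)), 8)
  for (r in unique(ev$run))
    expect_false(is.unsorted(ev$onset[ev$run == r], strictly = TRUE))
  expect_true(all(ev$duration > 0))
})

test_that("BOLD forward model is linear and noise-calibrated", {
  tpl <- make_city_templates(12, seed = 3)
  meta <- make_trial_meta(2)
  ev <- make_event_table(meta)
  hrf <- canonical_hrf(3)
  # single trial, noise off: series is template value x convolved regressor
  ev1 <- ev[1, , drop = FALSE]
  run1 <- simulate_bold_runs(ev1, matrix(tpl$templates[, 1], 1), hrf,
                             noise_sd = 0)[[1]]
  reg <- run1[, which.max(abs(tpl$templates[, 1]))] /
    tpl$templates[which.max(abs(tpl$templates[, 1])), 1]
  for (v in 1:12)
    expect_equal(run1[, v], reg * tpl$templates[v, 1], tolerance = 1e-10)

  # superposition: simulating two event subsets separately and summing
  # equals simulating them together
  ev2 <- ev[ev$run == 1, ]
  amp <- matrix(rnorm(nrow(ev2) * 12), nrow(ev2), 12)
  all_runs <- simulate_bold_runs(ev2, amp, hrf, noise_sd = 0)[[1]]
  half1 <- ev2[1:1, ]; half2 <- ev2[-1, ]
  r1 <- simulate_bold_runs(half1, amp[1, , drop = FALSE], hrf,
                           noise_sd = 0, pad_scans = 10)[[1]]
  r2 <- simulate_bold_runs(half2, amp[-1, , drop = FALSE], hrf,
                           noise_sd = 0, pad_scans = 10)[[1]]
  n <- min(nrow(r1), nrow(r2), nrow(all_runs))
  expect_equal(all_runs[1:n, ], r1[1:n, ] + r2[1:n, ], tolerance = 1e-10)

  # zero-amplitude templates: pure noise with sample sd ~ noise_sd
  rn <- simulate_bold_runs(ev2, matrix(0, nrow(ev2), 12), hrf,
                           noise_sd = 0.5, seed = 9)[[1]]
  expect_equal(sd(rn), 0.5, tolerance = 0.05)

  expect_error(simulate_bold_runs(ev2[0, ], amp[0, , drop = FALSE], hrf),
               "empty")
})

test_that("cohorts couple behaviour to attraction and validate inputs", {
  expect_error(simulate_cohort(1), "n_subjects")
  expect_error(simulate_cohort(5, p_attract_range = c(0.7, 0.2)),
               "p_attract_range")

  # no attraction, no lapse: perfect behaviour everywhere
  co0 <- simulate_cohort(3, p_attract_range = c(0, 0), n_voxels = 50,
                         lapse = 0, c3_instability = 0, seed = 2)
  for (s in co0) expect_equal(unname(s$behavior), rep(1, 4))

  # attraction driving City 3 behaviour down by ~p_attract
  co <- simulate_cohort(6, p_attract_range = c(0.4, 0.4), n_voxels = 50,
                        lapse = 0, seed = 3)
  beh3 <- sapply(co, function(s) s$behavior[["city3"]])
  expect_equal(mean(beh3), 0.6, tolerance = 0.1)
  # cohorts are seed-deterministic
  co2 <- simulate_cohort(6, p_attract_range = c(0.4, 0.4), n_voxels = 50,
                         lapse = 0, seed = 3)
  expect_identical(co[[2]]$patterns$matrix, co2[[2]]$patterns$matrix)
})

test_that("pattern datasets validate their invariants", {
  meta <- make_trial_meta(2)
  expect_error(pattern_dataset(matrix(0, 3, 4), meta), "rows")
  m <- matrix(0, nrow(meta), 4); m[1, 1] <- NA
  expect_error(pattern_dataset(m, meta), "finite")
  expect_error(simulate_trial_patterns(make_city_templates(10),
                                       noise_sd = -1), "noise_sd")
})
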