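#' Trial-wise pattern dataset
#'
#' The central exchange object of the pipeline: a trials x voxels matrix of
#' single-trial response patterns plus aligned per-trial metadata. Produced
#' either by the synthetic generator ([simulate_trial_patterns()]) or by
#' single-trial GLM estimation ([estimate_single_trial_betas()]).
#'
#' @param mat numeric trials x voxels matrix, all entries finite.
#' @param meta data.frame with one row per trial and columns `city` (1..4),
#'   `block_half` ("A"/"B"), `triad_id` (integer stimulus identity),
#'   `correct` (logical), `attracted_to` (NA, 1 or 2) and `response_side`
#'   ("left"/"right").
#' @param voxel_coords optional integer matrix (voxels x 3) of 0-based grid
#'   coordinates, one row per voxel.
#' @param roi_labels optional integer vector of per-voxel ROI tags.
#' @return An object of class `pattern_dataset`.
#' @export
pattern_dataset <- function(mat, meta, voxel_coords = NULL, roi_labels = NULL) {
  mat <- as.matrix(mat)
  if (!is.numeric(mat) || any(!is.finite(mat)))
    stop("pattern matrix must be numeric with all entries finite")
  if (nrow(mat) != nrow(meta))
    stop(sprintf("pattern matrix has %d rows but metadata has %d trials",
                 nrow(mat), nrow(meta)))
  required <- c("city", "block_half", "triad_id", "correct",
                "attracted_to", "response_side")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols))
    stop("metadata is missing columns: ", paste(missing_cols, collapse = ", "))
  if (!all(meta$city %in% 1:4)) stop("`city` must be in 1..4")
  if (!all(meta$block_half %in% c("A", "B")))
    stop('`block_half` must be "A" or "B"')
  if (!is.null(voxel_coords)) {
    voxel_coords <- as.matrix(voxel_coords)
    if (nrow(voxel_coords) != ncol(mat))
      stop("`voxel_coords` must have one row per voxel")
  }
  if (!is.null(roi_labels) && length(roi_labels) != ncol(mat))
    stop("`roi_labels` must have one entry per voxel")
  structure(list(matrix = mat, meta = as.data.frame(meta),
                 voxel_coords = voxel_coords, roi_labels = roi_labels),
            class = "pattern_dataset")
}

#' @export
print.pattern_dataset <- function(x, ...) {
  cat(sprintf("pattern_dataset: %d trials x %d voxels\n",
              nrow(x$matrix), ncol(x$matrix)))
  tab <- table(city = x$meta$city, half = x$meta$block_half)
  print(tab)
  cat(sprintf("  correct trials: %d / %d\n",
              sum(x$meta$correct), nrow(x$meta)))
  if (!is.null(x$roi_labels))
    cat("  ROI labels: ", paste(sort(unique(x$roi_labels)), collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' Number of trials / voxels in a pattern dataset
#' @param x a `pattern_dataset`.
#' @return integer count.
#' @export
n_trials <- function(x) nrow(x$matrix)

#' @rdname n_trials
#' @export
n_voxels <- function(x) ncol(x$matrix)

#' Trial design skeleton for the four-city retrieval task
#'
#' Builds the per-trial metadata of the retrieval design: 4 cities x 2
#' retrieval block halves ("A" and "B") x `n_trials_per_half` distance
#' judgements. Cities 1-3 share one stimulus-triad pool (identical store
#' images); City 4 has a disjoint pool. The probe stores of each triad are
#' swapped between the A and B blocks of a city, so the correct button
#' response for a triad flips between halves -- the design's control for
#' motor confounds.
#'
#' @param n_trials_per_half trials per retrieval block (default 20, the
#'   scanned design).
#' @return data.frame with columns `city`, `block_half`, `triad_id`,
#'   `correct` (initialised TRUE), `attracted_to` (initialised NA) and
#'   `response_side`.
#' @export
make_trial_meta <- function(n_trials_per_half = 20L) {
  if (n_trials_per_half < 1) stop("`n_trials_per_half` must be >= 1")
  n <- as.integer(n_trials_per_half)
  rows <- expand.grid(trial = seq_len(n), block_half = c("A", "B"),
                      city = 1:4, stringsAsFactors = FALSE)
  rows <- rows[order(rows$city, rows$block_half, rows$trial), ]
  # Cities 1-3 share triads 1..n; City 4 uses a disjoint pool.
  triad <- ifelse(rows$city == 4L, 1000L + rows$trial, rows$trial)
  side_a <- ifelse(rows$trial %% 2L == 1L, "left", "right")
  side <- ifelse(rows$block_half == "A", side_a,
                 ifelse(side_a == "left", "right", "left"))
  data.frame(city = rows$city, block_half = rows$block_half,
             triad_id = triad, correct = TRUE,
             attracted_to = NA_integer_, response_side = side,
             stringsAsFactors = FALSE)
}

#' Simulate single-trial voxel patterns for the four-city design
#'
#' Forward model at the pattern level: each trial's voxel pattern is its
#' city's template plus i.i.d. Gaussian noise. The interference city
#' (City 3) carries two failure mechanisms, mirroring the behaviour the
#' analysis is designed to detect:
#'
#' * **Full attraction** (`p_attract`): with this probability a City 3
#'   trial's pattern is generated from the City 1 or City 2 template
#'   (chosen uniformly) instead of its own -- the stored representation of
#'   a competing environment wins retrieval outright. Such trials are
#'   answered incorrectly (`correct = FALSE`) and record the competing
#'   city in `attracted_to`.
#' * **Partial instability** (`c3_instability`): even correctly answered
#'   City 3 trials can rest on a weakly separated code. Their signal is
#'   `unit((1 - mu) * T3 + mu * T_a)` with `T_a` a per-trial uniform draw
#'   from the City 1/2 templates, and their noise is scaled by
#'   `c3_noise_scale`. With `c3_instability = 0` (the default) City 3
#'   behaves exactly like the other cities apart from `p_attract`.
#'
#' All other trials are correct except an optional independent behavioural
#' `lapse` rate, which flips `correct` without touching the pattern.
#'
#' @param templates a `city_templates` object.
#' @param n_trials_per_half trials per retrieval block half (default 20).
#' @param noise_sd per-voxel Gaussian noise standard deviation (>= 0).
#'   Templates are unit-norm, so the expected within-city trial-pair
#'   correlation is approximately `1 / (1 + noise_sd^2 * n_voxels)`.
#' @param p_attract probability that a City 3 trial is fully attracted to
#'   City 1 or 2.
#' @param seed integer seed.
#' @param lapse independent behavioural lapse probability (default 0).
#' @param c3_instability mixing weight `mu` in `[0, 1]` pulling correct
#'   City 3 trial signals toward a randomly chosen similar-city template.
#' @param c3_noise_scale multiplier on `noise_sd` for correct City 3 trials
#'   (>= 1 models the noisier, unstable interference-city code).
#' @param geometry optional geometry from [make_default_geometry()]; when
#'   supplied (and matching `n_voxels`), voxel coordinates and ROI labels
#'   are attached so searchlight and ROI code paths both run.
#' @return a [pattern_dataset()].
#' @examples
#' tpl <- make_city_templates(100, seed = 1)
#' ds <- simulate_trial_patterns(tpl, noise_sd = 0.1, p_attract = 0.4,
#'                               seed = 2)
#' table(ds$meta$city, ds$meta$correct)
#' @export
simulate_trial_patterns <- function(templates, n_trials_per_half = 20L,
                                    noise_sd = 0.15, p_attract = 0,
                                    seed = 1L, lapse = 0,
                                    c3_instability = 0, c3_noise_scale = 1,
                                    geometry = NULL) {
  if (!inherits(templates, "city_templates"))
    stop("`templates` must be a `city_templates` object")
  if (noise_sd < 0) stop("`noise_sd` must be nonnegative")
  stopifnot_scalar_(p_attract, "p_attract", 0, 1)
  stopifnot_scalar_(lapse, "lapse", 0, 1)
  stopifnot_scalar_(c3_instability, "c3_instability", 0, 1)
  if (c3_noise_scale < 0) stop("`c3_noise_scale` must be nonnegative")

  meta <- make_trial_meta(n_trials_per_half)
  tpl <- templates$templates
  nv <- templates$n_voxels
  nt <- nrow(meta)

  out <- with_seed_(seed, {
    signal <- matrix(0, nt, nv)
    sdvec <- rep(noise_sd, nt)
    for (i in seq_len(nt)) {
      city <- meta$city[i]
      if (city == 3L && stats::runif(1) < p_attract) {
        a <- sample(1:2, 1L)
        signal[i, ] <- tpl[, a]
        meta$correct[i] <- FALSE
        meta$attracted_to[i] <- a
      } else if (city == 3L && c3_instability > 0) {
        a <- sample(1:2, 1L)
        mu <- c3_instability
        signal[i, ] <- unit_((1 - mu) * tpl[, 3L] + mu * tpl[, a])
        sdvec[i] <- noise_sd * c3_noise_scale
      } else {
        signal[i, ] <- tpl[, city]
      }
    }
    if (lapse > 0) {
      lapses <- stats::runif(nt) < lapse
      meta$correct[meta$correct & lapses] <- FALSE
    }
    noise <- matrix(stats::rnorm(nt * nv), nt, nv) * sdvec
    list(mat = signal + noise, meta = meta)
  })

  voxel_coords <- NULL
  roi_labels <- NULL
  if (!is.null(geometry)) {
    if (nrow(geometry$voxel_coords) != nv)
      stop("geometry voxel count does not match template `n_voxels`")
    voxel_coords <- geometry$voxel_coords
    roi_labels <- geometry$roi_labels
  }
  pattern_dataset(out$mat, out$meta, voxel_coords, roi_labels)
}

#' Default synthetic scan geometry
#'
#' A 12 x 12 x 8 voxel grid with an interior 6 x 6 x 4 block labelled as a
#' synthetic "ROI" (label 2; background in-mask voxels are label 1), so
#' that both the searchlight and the ROI-based code paths can be exercised
#' on one dataset.
#'
#' @param dims integer length-3 grid dimensions.
#' @param roi_corner 0-based corner of the ROI block.
#' @param roi_dims extents of the ROI block.
#' @return list with `dims`, `mask` (3D integer array), `voxel_coords`
#'   (voxels x 3, 0-based, one row per in-mask voxel in array order) and
#'   `roi_labels` (per-voxel labels aligned to `voxel_coords`).
#' @export
make_default_geometry <- function(dims = c(12L, 12L, 8L),
                                  roi_corner = c(3L, 3L, 2L),
                                  roi_dims = c(6L, 6L, 4L)) {
  dims <- as.integer(dims)
  mask <- array(1L, dim = dims)
  ix <- roi_corner[1] + seq_len(roi_dims[1])
  iy <- roi_corner[2] + seq_len(roi_dims[2])
  iz <- roi_corner[3] + seq_len(roi_dims[3])
  mask[ix, iy, iz] <- 2L
  coords <- as.matrix(expand.grid(x = seq_len(dims[1]) - 1L,
                                  y = seq_len(dims[2]) - 1L,
                                  z = seq_len(dims[3]) - 1L))
  list(dims = dims, mask = mask, voxel_coords = coords,
       roi_labels = as.integer(mask))
}

#' Simulate a cohort of subjects with coupled neural and behavioural data
#'
#' Draws one synthetic subject per seat: subject-specific city templates,
#' a trial-pattern dataset, and per-city behavioural retrieval accuracy
#' scored from the same generated trials (so neural attraction and
#' behavioural error share one cause, as the interference account
#' predicts). Each subject's City 3 attraction probability `p_attract` is
#' drawn uniformly from `p_attract_range`; City 3 behavioural accuracy is
#' therefore `1 - p_attract` up to binomial noise at 40 trials, and the
#' other cities sit at `1 - lapse`.
#'
#' The instability of a subject's City 3 code scales with how often that
#' subject is attracted: the mixing weight applied to correct City 3
#' trials is `min(1, c3_instability * p_attract / 0.4)`, i.e.
#' `c3_instability` is the instability of a subject at the reference
#' attraction rate 0.4. This one-parameter coupling encodes the
#' interference account's prediction that better performers hold more
#' separated interference-city representations.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param p_attract_range length-2 range for per-subject `p_attract`.
#' @param n_voxels voxels per subject.
#' @param noise_sd,separation,attraction_mix,c3_instability,c3_noise_scale,lapse
#'   passed to the per-subject generators; see
#'   [simulate_trial_patterns()] and [make_city_templates()]. Defaults are
#'   the package's reference study conditions (see the methods vignette).
#' @param n_trials_per_half trials per block half.
#' @param seed integer seed for the whole cohort.
#' @return object of class `cohort`: a list of subjects, each a list with
#'   `patterns` (a `pattern_dataset`), `behavior` (named per-city accuracy)
#'   and `p_attract`.
#' @export
simulate_cohort <- function(n_subjects, p_attract_range = c(0.15, 0.65),
                            n_voxels = 500L, noise_sd = 0.15,
                            separation = 1, attraction_mix = 0,
                            c3_instability = 0.7, c3_noise_scale = 1.5,
                            lapse = 0.08, n_trials_per_half = 20L,
                            seed = 1L) {
  if (!is.numeric(n_subjects) || length(n_subjects) != 1L || n_subjects < 2)
    stop("`n_subjects` must be >= 2")
  if (length(p_attract_range) != 2L || any(!is.finite(p_attract_range)) ||
      p_attract_range[1] > p_attract_range[2] ||
      p_attract_range[1] < 0 || p_attract_range[2] > 1)
    stop("`p_attract_range` must be an ordered pair within [0, 1]")
  n_subjects <- as.integer(n_subjects)

  subjects <- with_seed_(seed, {
    sub_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n_subjects)
    p_att <- stats::runif(n_subjects, p_attract_range[1], p_attract_range[2])
    lapply(seq_len(n_subjects), function(i) {
      tpl <- make_city_templates(n_voxels, separation = separation,
                                 attraction_mix = attraction_mix,
                                 seed = sub_seeds[2L * i - 1L])
      mu_i <- min(1, c3_instability * p_att[i] / 0.4)
      ds <- simulate_trial_patterns(
        tpl, n_trials_per_half = n_trials_per_half, noise_sd = noise_sd,
        p_attract = p_att[i], seed = sub_seeds[2L * i], lapse = lapse,
        c3_instability = mu_i, c3_noise_scale = c3_noise_scale)
      beh <- tapply(ds$meta$correct, ds$meta$city, mean)
      list(patterns = ds, behavior = stats::setNames(as.numeric(beh),
                                                     paste0("city", 1:4)),
           p_attract = p_att[i], templates = tpl)
    })
  })
  structure(subjects, class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d subjects, %d voxels each\n",
              length(x), n_voxels(x[[1]]$patterns)))
  beh <- t(vapply(x, `[[`, numeric(4), "behavior"))
  cat("  mean behavioural accuracy per city:\n")
  print(round(colMeans(beh), 3))
  invisible(x)
}
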