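#' Fisher z transform of a correlation
#'
#' `z = atanh(r)`, the variance-stabilising transform applied to every
#' trial-pair correlation before averaging.
#'
#' @param r correlation(s), strictly inside (-1, 1).
#' @return z value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) stop("|r| must be < 1 for the Fisher z transform")
  atanh(r)
}

#' Match trial pairs between (or within) cities
#'
#' Builds the list of trial pairs whose pattern correlations enter a
#' multivariate pattern similarity (MPS) cell.
#'
#' * `"triad_matched"` pairs trials showing the same stimulus triad, one
#'   from an A retrieval block and one from a B block -- within a city
#'   this is the similarity of the same judgement across the two halves
#'   (with opposite motor responses), and between Cities 1-3 (which share
#'   a stimulus set) it holds the visual stimulus constant. Triads present
#'   in only one half are excluded.
#' * `"all_pairwise"` takes the full cross product of eligible trials
#'   regardless of triad or half -- the scheme required for comparisons
#'   involving City 4, whose stimulus set is disjoint.
#'
#' By default only correctly answered trials are eligible on both sides;
#' the interference analysis overrides this per side.
#'
#' @param dataset a [pattern_dataset()].
#' @param city_a,city_b cities in 1..4 (equal for within-city pairs).
#' @param scheme `"triad_matched"` or `"all_pairwise"`.
#' @param correct_a,correct_b trial filters per side: `TRUE` (correct
#'   only, default), `FALSE` (incorrect only) or `NA` (all trials).
#' @return data.frame with columns `i`, `j` (trial indices).
#' @export
match_trial_pairs <- function(dataset, city_a, city_b,
                              scheme = c("triad_matched", "all_pairwise"),
                              correct_a = TRUE, correct_b = TRUE) {
  scheme <- match.arg(scheme)
  meta <- dataset$meta
  pick <- function(city, correct_filter, half = NULL) {
    sel <- meta$city == city
    if (!is.na(correct_filter))
      sel <- sel & (meta$correct == correct_filter)
    if (!is.null(half)) sel <- sel & meta$block_half == half
    which(sel)
  }

  pairs <- if (scheme == "all_pairwise") {
    ia <- pick(city_a, correct_a)
    ib <- pick(city_b, correct_b)
    if (city_a == city_b) {
      g <- expand.grid(i = ia, j = ib)
      g[g$i < g$j, ]
    } else {
      expand.grid(i = ia, j = ib)
    }
  } else {
    halves <- list(c("A", "B"), c("B", "A"))
    if (city_a == city_b) halves <- halves[1]   # A x B once within a city
    do.call(rbind, lapply(halves, function(h) {
      ia <- pick(city_a, correct_a, h[1])
      ib <- pick(city_b, correct_b, h[2])
      g <- expand.grid(i = ia, j = ib)
      g[meta$triad_id[g$i] == meta$triad_id[g$j], ]
    }))
  }
  if (is.null(pairs) || nrow(pairs) == 0L)
    stop(sprintf("no valid %s pairs between city %d and city %d under the given correctness filters",
                 scheme, city_a, city_b))
  rownames(pairs) <- NULL
  pairs
}

#' Mean pattern similarity over matched trial pairs
#'
#' For each trial pair, the Pearson correlation of the two trials' voxel
#' patterns across the ROI voxels, Fisher z transformed, then averaged.
#' Pairs with a constant pattern are dropped with a warning; correlations
#' at the `|r| = 1` boundary (possible in noise-free synthetic data) are
#' clipped to `1 - 1e-7` before the transform and counted.
#'
#' @param dataset a [pattern_dataset()].
#' @param roi voxel indices (>= 2), or a single ROI label matched against
#'   the dataset's `roi_labels`.
#' @param pairs pair list from [match_trial_pairs()].
#' @return list with `mean_z`, `z` (per pair), `n_pairs`, `n_clipped`.
#' @export
mps <- function(dataset, roi, pairs) {
  voxels <- resolve_roi_(dataset, roi)
  if (length(voxels) < 2L) stop("ROI must contain at least 2 voxels")
  if (nrow(pairs) < 1L) stop("need at least one trial pair")
  X <- dataset$matrix[, voxels, drop = FALSE]
  sds <- apply(X, 1L, stats::sd)
  const <- sds[pairs$i] == 0 | sds[pairs$j] == 0
  if (any(const)) {
    warning(sprintf("%d pair(s) dropped: constant pattern", sum(const)))
    pairs <- pairs[!const, , drop = FALSE]
    if (!nrow(pairs)) stop("all pairs had constant patterns")
  }
  r <- vapply(seq_len(nrow(pairs)), function(k) {
    stats::cor(X[pairs$i[k], ], X[pairs$j[k], ])
  }, numeric(1))
  clipped <- abs(r) >= 1 - 1e-7
  r[clipped] <- sign(r[clipped]) * (1 - 1e-7)
  z <- atanh(r)
  list(mean_z = mean(z), z = z, n_pairs = length(z),
       n_clipped = sum(clipped))
}

resolve_roi_ <- function(dataset, roi) {
  if (length(roi) == 1L && !is.null(dataset$roi_labels) &&
      roi %in% dataset$roi_labels && !(roi %in% seq_len(n_voxels(dataset)) &&
                                       is.null(dataset$roi_labels))) {
    which(dataset$roi_labels == roi)
  } else {
    as.integer(roi)
  }
}

#' Within / between city similarity matrix
#'
#' The 4 x 4 matrix of mean Fisher-z pattern similarities for one ROI:
#' diagonal cells are within-city similarity (cross-block, triad-matched
#' pairs), off-diagonal cells between-city similarity. Under the `"auto"`
#' scheme, cells among Cities 1-3 are triad-matched (they share a stimulus
#' set) while any cell involving City 4 uses all pairwise combinations of
#' correct trials; `"all_pairwise"` forces the City 4 scheme everywhere
#' (the control analysis for the matching rule).
#'
#' @param dataset a [pattern_dataset()].
#' @param roi voxel indices or ROI label (see [mps()]).
#' @param scheme `"auto"` (default) or `"all_pairwise"`.
#' @return object of class `similarity_matrix`: list with `z` (4 x 4),
#'   `n_pairs` (4 x 4 counts), `scheme` (4 x 4 character), `roi`.
#' @export
similarity_matrix <- function(dataset, roi, scheme = c("auto", "all_pairwise")) {
  scheme <- match.arg(scheme)
  z <- matrix(NA_real_, 4L, 4L,
              dimnames = list(paste0("city", 1:4), paste0("city", 1:4)))
  counts <- matrix(0L, 4L, 4L, dimnames = dimnames(z))
  used <- matrix(NA_character_, 4L, 4L, dimnames = dimnames(z))
  for (a in 1:4) {
    for (b in a:4) {
      cell_scheme <- if (a == b) {
        "triad_matched"
      } else if (scheme == "all_pairwise" || a == 4L || b == 4L) {
        "all_pairwise"
      } else {
        "triad_matched"
      }
      pairs <- match_trial_pairs(dataset, a, b, scheme = cell_scheme)
      m <- mps(dataset, roi, pairs)
      z[a, b] <- z[b, a] <- m$mean_z
      counts[a, b] <- counts[b, a] <- m$n_pairs
      used[a, b] <- used[b, a] <- cell_scheme
    }
  }
  structure(list(z = z, n_pairs = counts, scheme = used, roi = roi),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat("similarity_matrix (mean Fisher z):\n")
  print(round(x$z, 4))
  invisible(x)
}

#' Remapping index of a city
#'
#' The operational definition of voxel-pattern remapping: within-city
#' similarity minus the average of that city's three between-city
#' similarities, on the Fisher-z scale. Positive values mean the ROI's
#' pattern is reinstated for the same environment and distinct from the
#' others; an index near zero means the environment's code is not
#' separated from its competitors.
#'
#' @param sim a [similarity_matrix()].
#' @param city city in 1..4, or omitted for all four.
#' @return scalar index, or a named length-4 vector from
#'   `remapping_indices()`.
#' @export
remapping_index <- function(sim, city) {
  if (!inherits(sim, "similarity_matrix"))
    stop("`sim` must be a `similarity_matrix`")
  if (any(is.na(sim$z[city, ])))
    stop("similarity matrix has missing cells for this city")
  sim$z[city, city] - mean(sim$z[city, -city])
}

#' @rdname remapping_index
#' @export
remapping_indices <- function(sim) {
  stats::setNames(vapply(1:4, function(c) remapping_index(sim, c),
                         numeric(1)), paste0("city", 1:4))
}

#' Interference analysis of incorrect interference-city trials
#'
#' Tests whether retrieval errors on the interference city (City 3) stem
#' from attraction toward the similar cities: if so, voxel patterns of
#' *incorrect* City 3 trials should resemble correct City 1/2 patterns
#' more than *correct* City 3 trials do, while neither should resemble
#' the distinct city (City 4). Four condition means are returned, all on
#' the Fisher-z scale:
#'
#' 1. incorrect City 3 x correct City 1/2 (triad-matched),
#' 2. correct City 3 x correct City 1/2 (triad-matched),
#' 3. incorrect City 3 x correct City 4 (all pairwise),
#' 4. correct City 3 x correct City 4 (all pairwise).
#'
#' @param dataset a [pattern_dataset()] (City 3 needs at least one
#'   incorrect and one correct trial).
#' @param roi voxel indices or ROI label.
#' @return object of class `interference_mps`: named numeric `means`
#'   (length 4) plus `n_pairs`.
#' @export
interference_trial_analysis <- function(dataset, roi) {
  meta <- dataset$meta
  c3 <- meta$city == 3L
  if (!any(c3 & !meta$correct))
    stop("empty condition: City 3 has no incorrect trials")
  if (!any(c3 & meta$correct))
    stop("empty condition: City 3 has no correct trials")

  sim_pairs <- function(correct3) {
    do.call(rbind, lapply(1:2, function(b) {
      match_trial_pairs(dataset, 3L, b, scheme = "triad_matched",
                        correct_a = correct3, correct_b = TRUE)
    }))
  }
  conds <- list(
    inc3_sim = sim_pairs(FALSE),
    cor3_sim = sim_pairs(TRUE),
    inc3_distinct = match_trial_pairs(dataset, 3L, 4L, "all_pairwise",
                                      correct_a = FALSE, correct_b = TRUE),
    cor3_distinct = match_trial_pairs(dataset, 3L, 4L, "all_pairwise",
                                      correct_a = TRUE, correct_b = TRUE)
  )
  res <- lapply(conds, function(p) mps(dataset, roi, p))
  structure(list(means = vapply(res, `[[`, numeric(1), "mean_z"),
                 n_pairs = vapply(res, `[[`, numeric(1), "n_pairs")),
            class = "interference_mps")
}

#' @export
print.interference_mps <- function(x, ...) {
  cat("interference_mps condition means (Fisher z):\n")
  print(round(x$means, 4))
  invisible(x)
}

#' Group test of the interference conditions
#'
#' Paired t-tests, across subjects, of the incorrect-City 3 x similar-city
#' condition against each other condition (two-tailed): the interference
#' account predicts condition 1 above all others.
#'
#' @param cond_means subjects x 4 matrix of per-subject condition means in
#'   the order returned by [interference_trial_analysis()].
#' @return data.frame with one row per comparison (`t`, `df`, `p`).
#' @export
interference_group_test <- function(cond_means) {
  cond_means <- as.matrix(cond_means)
  if (ncol(cond_means) != 4L) stop("expected 4 condition columns")
  comps <- lapply(2:4, function(j) {
    tt <- stats::t.test(cond_means[, 1], cond_means[, j], paired = TRUE)
    data.frame(comparison = paste0("inc3_sim_vs_", colnames(cond_means)[j]),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  })
  do.call(rbind, comps)
}

#' Univariate activation control
#'
#' Mean single-trial beta per ROI and city for each subject (correct
#' trials only), with a repeated-measures ANOVA testing the city main
#' effect and the ROI x city interaction. If multivariate effects merely
#' reflected overall activation differences between cities, this control
#' would show them; a null city effect supports a genuinely
#' pattern-based interpretation.
#'
#' @param datasets list of [pattern_dataset()]s, one per subject.
#' @param rois named list of voxel-index vectors (or ROI labels), length
#'   >= 2.
#' @return list with `table` (long data.frame: subject, roi, city, mean
#'   activation) and `anova` (data.frame of effects with `F`, `df`, `p`).
#' @export
univariate_control <- function(datasets, rois) {
  if (length(rois) < 2L) stop("need at least 2 ROIs")
  if (is.null(names(rois))) names(rois) <- paste0("roi", seq_along(rois))
  rows <- list()
  for (s in seq_along(datasets)) {
    ds <- datasets[[s]]
    for (rn in names(rois)) {
      voxels <- resolve_roi_(ds, rois[[rn]])
      for (city in 1:4) {
        sel <- ds$meta$city == city & ds$meta$correct
        if (!any(sel))
          stop(sprintf("subject %d city %d has no correct trials", s, city))
        rows[[length(rows) + 1L]] <- data.frame(
          subject = factor(s), roi = factor(rn), city = factor(city),
          activation = mean(ds$matrix[sel, voxels]))
      }
    }
  }
  tab <- do.call(rbind, rows)
  fit <- stats::aov(activation ~ roi * city + Error(subject / (roi * city)),
                    data = tab)
  sm <- summary(fit)
  effects <- do.call(rbind, lapply(sm, function(stratum) {
    a <- stratum[[1]]
    keep <- !grepl("Residuals", rownames(a))
    if (!any(keep)) return(NULL)
    data.frame(effect = trimws(rownames(a)[keep]),
               df = a$Df[keep],
               F = a$`F value`[keep],
               p = a$`Pr(>F)`[keep])
  }))
  rownames(effects) <- NULL
  list(table = tab, anova = effects)
}
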