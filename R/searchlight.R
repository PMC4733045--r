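#' Searchlight neighbourhoods on a labelled voxel grid
#'
#' Builds one local neighbourhood per in-mask voxel: the set of in-mask
#' voxels inside an ellipsoid centred on that voxel. The default semi-axes
#' `(2.2, 2.2, 1.5)` in voxel units are chosen so that an interior centre
#' on an unmasked grid contains exactly 31 voxels -- with the acquisition's
#' anisotropic 1.6 x 1.6 x 2 mm voxels this is a roughly spherical ~3.5 mm
#' region. Centres near the mask edge keep whatever members fall inside
#' the mask. If `target_size` differs from what the supplied semi-axes
#' yield, the axes are scaled uniformly (preserving their anisotropy)
#' until an interior centre hits the target.
#'
#' @param mask 3D integer array; voxels with values `> 0` are in-mask.
#' @param semi_axes length-3 ellipsoid semi-axes in voxel units.
#' @param target_size desired interior neighbourhood size (default 31).
#' @return list of neighbourhoods, each a list with `center` (index into
#'   the in-mask voxel list), `members` (indices into the same list, centre
#'   included) and `center_coord` (0-based grid coordinate).
#' @export
make_neighborhoods <- function(mask, semi_axes = c(2.2, 2.2, 1.5),
                               target_size = 31L) {
  if (target_size < 1) stop("`target_size` must be >= 1")
  dims <- dim(mask)
  if (length(dims) != 3L) stop("`mask` must be a 3D array")
  in_mask <- which(mask > 0)
  if (!length(in_mask)) stop("mask is empty")

  offsets <- ellipsoid_offsets_(semi_axes)
  if (nrow(offsets) != target_size) {
    semi_axes <- scale_axes_to_size_(semi_axes, target_size)
    offsets <- ellipsoid_offsets_(semi_axes)
  }

  # lookup from linear grid index to position in the in-mask voxel list
  lookup <- integer(prod(dims))
  lookup[in_mask] <- seq_along(in_mask)

  coords <- arrayInd(in_mask, dims) - 1L   # 0-based
  lapply(seq_along(in_mask), function(i) {
    nb <- sweep(offsets, 2L, coords[i, ], `+`)
    ok <- nb[, 1] >= 0 & nb[, 1] < dims[1] &
      nb[, 2] >= 0 & nb[, 2] < dims[2] &
      nb[, 3] >= 0 & nb[, 3] < dims[3]
    nb <- nb[ok, , drop = FALSE]
    lin <- 1L + nb[, 1] + dims[1] * (nb[, 2] + dims[2] * nb[, 3])
    members <- lookup[lin]
    members <- members[members > 0L]
    list(center = lookup[in_mask[i]], members = members,
         center_coord = coords[i, ])
  })
}

# Integer lattice offsets inside the ellipsoid with the given semi-axes.
ellipsoid_offsets_ <- function(semi_axes) {
  r <- floor(semi_axes)
  g <- as.matrix(expand.grid(x = -r[1]:r[1], y = -r[2]:r[2], z = -r[3]:r[3]))
  d <- (g[, 1] / semi_axes[1])^2 + (g[, 2] / semi_axes[2])^2 +
    (g[, 3] / semi_axes[3])^2
  g[d <= 1, , drop = FALSE]
}

# Uniformly scale semi-axes until the interior lattice count matches
# `target_size` (counts are monotone in the scale; scan a fine grid).
scale_axes_to_size_ <- function(semi_axes, target_size) {
  for (s in seq(0.3, 4, by = 0.01)) {
    if (nrow(ellipsoid_offsets_(semi_axes * s)) >= target_size) {
      if (nrow(ellipsoid_offsets_(semi_axes * s)) == target_size)
        return(semi_axes * s)
      break
    }
  }
  stop(sprintf("no uniform scaling of semi-axes (%s) hits %d lattice points",
               paste(semi_axes, collapse = ", "), target_size))
}

#' Split-half cross-validation folds over retrieval blocks
#'
#' The design has two retrieval blocks per city ("A" and "B" halves). The
#' classifier is trained on one half of the blocks (one block per city)
#' and tested on the other half, then the halves are swapped: fold 1
#' trains on all A blocks and tests on B, fold 2 the reverse. Only
#' correctly answered trials enter training; every test trial is scored
#' (incorrect trials are flagged so the interference analyses can use
#' them).
#'
#' @param dataset a [pattern_dataset()].
#' @return list of two folds, each a list with integer `train` and `test`
#'   trial indices.
#' @export
split_half_folds <- function(dataset) {
  meta <- dataset$meta
  for (city in 1:4) {
    for (half in c("A", "B")) {
      sel <- meta$city == city & meta$block_half == half
      if (!any(sel))
        stop(sprintf("city %d has no trials in half %s", city, half))
      if (!any(meta$correct[sel]))
        stop(sprintf("city %d has no correct trials in half %s (cannot train)",
                     city, half))
    }
  }
  fold_for <- function(train_half, test_half) {
    list(train = which(meta$block_half == train_half & meta$correct),
         test = which(meta$block_half == test_half))
  }
  list(fold_for("A", "B"), fold_for("B", "A"))
}

#' Balance training trials across cities
#'
#' Reduces each city's training set to the minimum per-city count by
#' uniform sampling without replacement, so the classifier sees the same
#' number of trials from each environment (the balanced-training control
#' protocol).
#'
#' @param train_idx integer trial indices of the training set.
#' @param cities city labels aligned with `train_idx`.
#' @param seed integer seed (same seed, same subset).
#' @return subset of `train_idx`.
#' @export
balance_training <- function(train_idx, cities, seed = 1L) {
  stopifnot(length(train_idx) == length(cities))
  counts <- table(factor(cities, levels = 1:4))
  if (any(counts == 0))
    stop("every city needs at least one training trial to balance")
  m <- min(counts)
  with_seed_(seed, {
    keep <- unlist(lapply(1:4, function(city) {
      idx <- train_idx[cities == city]
      if (length(idx) == m) idx else sample(idx, m)
    }))
    sort(keep)
  })
}

#' Cross-validated environment classification of a voxel set
#'
#' Trains a 4-way environment classifier on the training trials of each
#' fold, restricted to the given voxels, predicts the fold's test trials,
#' and pools the confusion counts over folds. The default model is
#' multinomial logistic regression, a deterministic stand-in for
#' underspecified backpropagation networks: the claims under test concern
#' the information content of the patterns, not the classifier family. A
#' small multilayer perceptron (`model = "mlp"`) is available for
#' sensitivity checks. Exact score ties are broken toward the lowest city
#' index.
#'
#' @param dataset a [pattern_dataset()].
#' @param voxels integer voxel indices (default: all voxels).
#' @param folds folds from [split_half_folds()] (computed if `NULL`).
#' @param model `"logistic"` (default) or `"mlp"`.
#' @param balanced if `TRUE`, training trials are balanced across cities
#'   with [balance_training()].
#' @param seed seed for balancing and MLP initialisation.
#' @param hidden hidden-layer size for the MLP.
#' @return list of class `city_classification`: `confusion` (4 x 4 counts,
#'   rows = true city, columns = predicted), `overall_accuracy`,
#'   `per_city_accuracy` (length 4), `flagged` (TRUE if the voxel set was
#'   degenerate and no model could be fit).
#' @export
classify_patterns <- function(dataset, voxels = NULL, folds = NULL,
                              model = c("logistic", "mlp"),
                              balanced = FALSE, seed = 1L, hidden = 8L) {
  model <- match.arg(model)
  if (is.null(folds)) folds <- split_half_folds(dataset)
  if (is.null(voxels)) voxels <- seq_len(n_voxels(dataset))
  X <- dataset$matrix[, voxels, drop = FALSE]
  meta <- dataset$meta

  conf <- matrix(0L, 4L, 4L,
                 dimnames = list(true = paste0("city", 1:4),
                                 pred = paste0("city", 1:4)))
  flagged <- FALSE
  for (f in seq_along(folds)) {
    train <- folds[[f]]$train
    test <- folds[[f]]$test
    if (balanced)
      train <- balance_training(train, meta$city[train],
                                seed = seed + f)
    Xtr <- X[train, , drop = FALSE]
    keep <- col_sds_(Xtr) > 0
    if (!any(keep)) { flagged <- TRUE; next }
    if (length(unique(meta$city[train])) < 2L)
      stop("training fold has fewer than 2 classes")
    probs <- fit_predict_city_(Xtr[, keep, drop = FALSE], meta$city[train],
                               X[test, keep, drop = FALSE], model,
                               seed = seed, hidden = hidden)
    pred <- max.col(probs, ties.method = "first")  # tie -> lowest city index
    for (i in seq_along(test))
      conf[meta$city[test[i]], pred[i]] <- conf[meta$city[test[i]], pred[i]] + 1L
  }
  per_city <- diag(conf) / rowSums(conf)
  structure(list(confusion = conf,
                 overall_accuracy = sum(diag(conf)) / sum(conf),
                 per_city_accuracy = per_city, flagged = flagged),
            class = "city_classification")
}

# Fit the configured model and return a test x 4 matrix of class scores
# with columns ordered city 1..4. Fits are wrapped in a fixed local RNG
# state so results are reproducible for a given input.
fit_predict_city_ <- function(Xtr, ytr, Xte, model, seed = 1L, hidden = 8L) {
  df_tr <- as.data.frame(Xtr)
  names(df_tr) <- paste0("v", seq_len(ncol(Xtr)))
  df_te <- as.data.frame(Xte)
  names(df_te) <- names(df_tr)
  y <- factor(ytr, levels = 1:4)
  present <- levels(droplevels(y))
  probs <- matrix(0, nrow(Xte), 4L)
  with_seed_(seed, {
    if (model == "logistic") {
      fit <- nnet::multinom(y ~ ., data = cbind(y = droplevels(y), df_tr),
                            trace = FALSE, maxit = 200, MaxNWts = 1e5,
                            decay = 1e-4)
    } else {
      fit <- nnet::nnet(y ~ ., data = cbind(y = droplevels(y), df_tr),
                        size = hidden, trace = FALSE,
                        maxit = 300, decay = 1e-3, MaxNWts = 1e5)
    }
    p <- stats::predict(fit, newdata = df_te,
                        type = if (model == "logistic") "probs" else "raw")
    if (is.null(dim(p))) {  # two-class fits return a vector
      p <- cbind(1 - p, p)
      colnames(p) <- present
    }
    probs[, as.integer(present)] <- p[, present, drop = FALSE]
  })
  probs
}

#' @export
print.city_classification <- function(x, ...) {
  cat(sprintf("city_classification: overall accuracy %.3f\n",
              x$overall_accuracy))
  cat("  per-city: ", paste(sprintf("%.3f", x$per_city_accuracy),
                            collapse = " "), "\n")
  print(x$confusion)
  invisible(x)
}

#' Run a searchlight classification map
#'
#' Applies [classify_patterns()] within every neighbourhood, producing a
#' per-centre accuracy map, per-centre per-city accuracies, and the
#' confusion counts pooled over all centres. Degenerate neighbourhoods
#' (all-constant features) are flagged, not fatal.
#'
#' @param dataset a [pattern_dataset()] with voxel coordinates.
#' @param neighborhoods from [make_neighborhoods()].
#' @param ... passed to [classify_patterns()].
#' @return object of class `searchlight_result`: list with `accuracy`
#'   (per centre), `per_city` (centres x 4), `confusion` (pooled 4 x 4),
#'   `centers` (centre voxel indices), `flagged` (logical per centre).
#' @export
run_searchlight <- function(dataset, neighborhoods, ...) {
  folds <- split_half_folds(dataset)
  n <- length(neighborhoods)
  acc <- numeric(n)
  per_city <- matrix(NA_real_, n, 4L)
  flagged <- logical(n)
  pooled <- matrix(0L, 4L, 4L,
                   dimnames = list(true = paste0("city", 1:4),
                                   pred = paste0("city", 1:4)))
  for (i in seq_len(n)) {
    res <- classify_patterns(dataset, voxels = neighborhoods[[i]]$members,
                             folds = folds, ...)
    acc[i] <- res$overall_accuracy
    per_city[i, ] <- res$per_city_accuracy
    flagged[i] <- res$flagged
    pooled <- pooled + res$confusion
  }
  structure(list(accuracy = acc, per_city = per_city, confusion = pooled,
                 centers = vapply(neighborhoods, `[[`, integer(1), "center"),
                 flagged = flagged),
            class = "searchlight_result")
}

#' Misclassification rate toward a target set of cities
#'
#' Fraction of a source city's test trials that the classifier labelled as
#' any member of `targets` -- e.g. the fraction of interference-city
#' (City 3) trials labelled as one of the similar cities (Cities 1 and 2),
#' whose chance level under a uniform random 4-way predictor is 0.5.
#'
#' @param confusion 4 x 4 confusion counts (rows = true city).
#' @param source source city (row).
#' @param targets predicted cities to count (columns).
#' @param denominator `"all"` (default: all source trials, consistent with
#'   a "more than 50% of trials" chance level) or `"misclassified"` (only
#'   source trials the classifier got wrong).
#' @return fraction in `[0, 1]`.
#' @export
misclassification_rate <- function(confusion, source, targets,
                                   denominator = c("all", "misclassified")) {
  denominator <- match.arg(denominator)
  row <- confusion[source, ]
  denom <- if (denominator == "all") sum(row) else sum(row[-source])
  if (denom == 0) stop("source city has no (mis)classified trials")
  sum(row[targets]) / denom
}

#' Across-subject correlation of behaviour and decoding
#'
#' Standard Pearson correlation (with the two-sided t-based p-value at
#' `n - 2` degrees of freedom) between per-subject behavioural retrieval
#' accuracy and per-subject classifier accuracy -- the test that links
#' interference-city behaviour to the stability of its neural code.
#'
#' @param behavioral numeric vector, one accuracy per subject.
#' @param decoding numeric vector, same length.
#' @return list with `r`, `p`, `df`.
#' @export
behavior_classifier_correlation <- function(behavioral, decoding) {
  if (length(behavioral) != length(decoding))
    stop("inputs must have one value per subject each")
  if (length(behavioral) < 3L) stop("need at least 3 subjects")
  if (stats::sd(behavioral) == 0 || stats::sd(decoding) == 0)
    stop("inputs must have nonzero variance")
  ct <- stats::cor.test(behavioral, decoding, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value,
       df = unname(ct$parameter))
}
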