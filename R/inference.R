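#' One-sample t-map over subjects
#'
#' Voxelwise one-sample t statistic of subject maps against a chance
#' level (e.g. accuracy maps against 0.25). Subject maps are assumed
#' already aligned on a common grid. Zero-variance voxels have an
#' undefined t and are masked out (`NA`) with a warning.
#'
#' @param maps subjects x voxels matrix of aligned statistic maps.
#' @param chance scalar chance level subtracted from every value.
#' @return object of class `group_map`: list with `t` (per-voxel t, `NA`
#'   where masked), `df` (`n_subjects - 1`), `n_subjects`, `chance`.
#' @export
one_sample_tmap <- function(maps, chance) {
  maps <- as.matrix(maps)
  n <- nrow(maps)
  if (n < 3L) stop("need at least 3 subjects for a group t-map")
  d <- maps - chance
  mu <- colMeans(d)
  s <- col_sds_(d)
  t <- rep(NA_real_, ncol(maps))
  ok <- s > 0
  if (any(!ok))
    warning(sprintf("%d zero-variance voxel(s) masked out", sum(!ok)))
  t[ok] <- mu[ok] / (s[ok] / sqrt(n))
  structure(list(t = t, df = n - 1L, n_subjects = n, chance = chance),
            class = "group_map")
}

#' Connected supra-threshold clusters on a 3D grid
#'
#' Thresholds a statistic map laid out on a 3D grid and returns the
#' connected components of the supra-threshold voxels under the requested
#' neighbourhood connectivity (6 = faces, 18 = faces + edges,
#' 26 = faces + edges + corners).
#'
#' @param tvals per-voxel statistic, in array order for `dims`.
#' @param dims length-3 grid dimensions (`prod(dims) == length(tvals)`).
#' @param t_threshold cluster-forming threshold; voxels with
#'   `tvals >= t_threshold` enter clusters (`NA` voxels never do).
#' @param connectivity 6, 18 or 26 (default 18, a common neuroimaging
#'   choice).
#' @return list of clusters, each a list with `voxels` (linear indices),
#'   `size` and `peak` (maximum statistic); ordered by decreasing size.
#' @export
form_clusters <- function(tvals, dims, t_threshold, connectivity = 18L) {
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("`connectivity` must be 6, 18 or 26")
  if (!is.finite(t_threshold)) stop("`t_threshold` must be finite")
  if (prod(dims) != length(tvals))
    stop("`dims` does not match the map length")
  supra <- which(!is.na(tvals) & tvals >= t_threshold)
  if (!length(supra)) return(list())

  offs <- connectivity_offsets_(connectivity)
  in_set <- logical(prod(dims))
  in_set[supra] <- TRUE
  visited <- logical(prod(dims))
  clusters <- list()
  coords_all <- arrayInd(supra, dims)
  coord_of <- function(lin) arrayInd(lin, dims)[1, ]

  for (v in supra) {
    if (visited[v]) next
    # breadth-first flood fill from v
    queue <- v
    visited[v] <- TRUE
    members <- integer(0)
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      members <- c(members, cur)
      cc <- coord_of(cur)
      nb <- sweep(offs, 2L, cc, `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
        nb[, 2] >= 1 & nb[, 2] <= dims[2] &
        nb[, 3] >= 1 & nb[, 3] <= dims[3]
      lin <- nb[ok, 1] + dims[1] * (nb[ok, 2] - 1L) +
        dims[1] * dims[2] * (nb[ok, 3] - 1L)
      new <- lin[in_set[lin] & !visited[lin]]
      visited[new] <- TRUE
      queue <- c(queue, new)
    }
    clusters[[length(clusters) + 1L]] <-
      list(voxels = sort(members), size = length(members),
           peak = max(tvals[members]))
  }
  clusters[order(vapply(clusters, `[[`, integer(1), "size"),
                 decreasing = TRUE)]
}

connectivity_offsets_ <- function(connectivity) {
  g <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  d <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = d == 1, "18" = d >= 1 & d <= 2, "26" = d >= 1)
  g[keep, , drop = FALSE]
}

#' Max-cluster-size permutation correction for a group map
#'
#' Family-wise error control for cluster inference: each permutation
#' randomly sign-flips every subject's deviation from chance, recomputes
#' the group t-map, thresholds and clusters it, and records the maximum
#' cluster size. The corrected size threshold is the 95th percentile of
#' that null distribution; observed clusters are reported with their
#' permutation p-value `(1 + #\{null >= size\}) / (n_perm + 1)` and
#' survive at corrected `p < 0.05`. Sign-flipping is the standard
#' exchangeable null for a one-sample group test.
#'
#' @param maps subjects x voxels matrix (voxels in array order for
#'   `dims`).
#' @param dims length-3 grid dimensions.
#' @param chance chance level.
#' @param t_threshold cluster-forming threshold; default is the one-tailed
#'   Student quantile at `alpha_form` and `df = n - 1` -- the group
#'   hypothesis (above-chance decoding) is directional, and the denser
#'   supra-threshold maps also temper the tie-induced conservatism of the
#'   discrete max-size null. A two-tailed variant is available via
#'   `tail = "two"`.
#' @param alpha_form cluster-forming alpha (default 0.05).
#' @param tail `"one"` (default) or `"two"` for the forming threshold.
#' @param n_perm number of permutations (default 1000; fewer than 100
#'   draws a warning).
#' @param connectivity cluster connectivity (default 18).
#' @param seed mandatory integer seed.
#' @return object of class `cluster_report`: list with `clusters` (each
#'   with `voxels`, `size`, `peak`, `p_corrected`, `survives`),
#'   `size_threshold` (95th percentile of the null max sizes),
#'   `t_threshold`, `null_max_sizes`, `n_perm`.
#' @export
max_cluster_permutation <- function(maps, dims, chance, t_threshold = NULL,
                                    alpha_form = 0.05,
                                    tail = c("one", "two"),
                                    n_perm = 1000L, connectivity = 18L,
                                    seed) {
  if (missing(seed)) stop("`seed` is mandatory for reproducibility")
  tail <- match.arg(tail)
  maps <- as.matrix(maps)
  n <- nrow(maps)
  if (n < 5L) stop("need at least 5 subjects for meaningful sign-flips")
  if (n_perm < 100L) warning("fewer than 100 permutations is unreliable")
  df <- n - 1L
  if (is.null(t_threshold)) {
    p_form <- if (tail == "two") 1 - alpha_form / 2 else 1 - alpha_form
    t_threshold <- stats::qt(p_form, df)
  }

  d <- maps - chance
  sumsq <- colSums(d^2)          # invariant under sign flips
  tmap_from_signs <- function(s) {
    mu <- as.numeric(s %*% d) / n
    varv <- (sumsq - n * mu^2) / (n - 1)
    t <- rep(NA_real_, length(mu))
    ok <- varv > 0
    t[ok] <- mu[ok] / sqrt(varv[ok] / n)
    t
  }

  obs_t <- tmap_from_signs(rep(1, n))
  obs_clusters <- form_clusters(obs_t, dims, t_threshold, connectivity)

  null_max <- with_seed_(seed, {
    vapply(seq_len(n_perm), function(i) {
      s <- sample(c(-1, 1), n, replace = TRUE)
      cl <- form_clusters(tmap_from_signs(s), dims, t_threshold,
                          connectivity)
      if (length(cl)) max(vapply(cl, `[[`, integer(1), "size")) else 0L
    }, integer(1))
  })

  size_threshold <- stats::quantile(null_max, 0.95, type = 1, names = FALSE)
  clusters <- lapply(obs_clusters, function(cl) {
    cl$p_corrected <- (1 + sum(null_max >= cl$size)) / (n_perm + 1)
    cl$survives <- cl$p_corrected < 0.05
    cl
  })
  structure(list(clusters = clusters, size_threshold = size_threshold,
                 t_threshold = t_threshold, null_max_sizes = null_max,
                 n_perm = as.integer(n_perm), df = df),
            class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  surv <- sum(vapply(x$clusters, `[[`, logical(1), "survives"))
  cat(sprintf("cluster_report: %d supra-threshold cluster(s), %d survive FWE\n",
              length(x$clusters), surv))
  cat(sprintf("  forming t >= %.3f (df = %d), corrected size threshold %d (%d perms)\n",
              x$t_threshold, x$df, x$size_threshold, x$n_perm))
  invisible(x)
}

#' Bootstrap family-wise-corrected t threshold
#'
#' Max-statistic correction for a family of one-sample t-tests (e.g. one
#' per subfield and city): each iteration sign-flips every subject's
#' values and records the maximum |t| across all conditions; the corrected
#' threshold is the requested percentile of that max-|t| distribution.
#' Flips are applied per subject jointly across conditions, preserving the
#' within-subject dependence of the family (a per-cell variant is
#' available).
#'
#' @param data conditions x subjects matrix of the values each t-test is
#'   run on (already centred on the tested null value).
#' @param n_iter iterations (default 10000).
#' @param percentile percentile of the max-|t| distribution (default 95).
#' @param flip `"subject"` (default, joint flips) or `"cell"`.
#' @param seed integer seed.
#' @return corrected |t| threshold (scalar), with the null max-|t| draws
#'   attached as attribute `"null_max_t"`.
#' @export
bootstrap_fwe_tthreshold <- function(data, n_iter = 10000L, percentile = 95,
                                     flip = c("subject", "cell"), seed = 1L) {
  flip <- match.arg(flip)
  data <- as.matrix(data)
  n_cond <- nrow(data)
  n_sub <- ncol(data)
  if (n_sub < 2L) stop("need at least 2 subjects")
  if (n_cond < 1L) stop("need at least 1 condition")

  sumsq <- rowSums(data^2)       # per condition, invariant under flips
  max_t <- with_seed_(seed, {
    if (flip == "subject") {
      S <- matrix(sample(c(-1, 1), n_iter * n_sub, replace = TRUE),
                  n_iter, n_sub)
      mu <- tcrossprod(S, data) / n_sub        # iter x cond means
    } else {
      mu <- matrix(0, n_iter, n_cond)
      for (c in seq_len(n_cond)) {
        S <- matrix(sample(c(-1, 1), n_iter * n_sub, replace = TRUE),
                    n_iter, n_sub)
        mu[, c] <- as.numeric(S %*% data[c, ]) / n_sub
      }
    }
    varm <- sweep(-n_sub * mu^2, 2L, sumsq, `+`) / (n_sub - 1)
    tmat <- abs(mu) / sqrt(varm / n_sub)
    tmat[varm <= 0] <- 0
    apply(tmat, 1L, max)
  })
  thr <- stats::quantile(max_t, percentile / 100, names = FALSE)
  attr(thr, "null_max_t") <- max_t
  thr
}
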