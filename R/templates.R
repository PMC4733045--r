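#' Ground-truth voxel templates for the four-city design
#'
#' Generates one voxel response template per virtual environment ("city").
#' The four-environment layout mirrors the retrieval design this package
#' analyses: Cities 1 and 2 are the "similar" cities (same stores, two
#' swapped), City 3 is the "interference" city (same stores, novel layout),
#' and City 4 is the "distinct" city (novel stores and layout). At the voxel
#' level the generative model is deliberately simple: templates are
#' unit-norm Gaussian vectors, so that codes for different cities are
#' mutually (near-)orthogonal by construction, which is exactly the
#' statistical structure a remapping analysis assumes under the null of
#' fully separated codes.
#'
#' Two dials control departures from full separation:
#'
#' * `separation` sets the expected correlation distance between any pair of
#'   templates. `separation = 1` (default) gives independent templates
#'   (expected pairwise correlation 0); `separation = 0` collapses all four
#'   templates onto one shared pattern. Intermediate values mix a shared
#'   component into every template so the expected between-city template
#'   correlation is approximately `1 - separation`.
#' * `attraction_mix` (lambda) draws City 3's template toward the average of
#'   the City 1 and City 2 templates:
#'   `T3 = lambda * unit(mean(T1, T2)) + (1 - lambda) * U3` with `U3` an
#'   independent draw. With orthogonal components the correlation of `T3`
#'   with `mean(T1, T2)` is `lambda / sqrt(lambda^2 + (1 - lambda)^2)`.
#'
#' @param n_voxels number of voxels (>= 2).
#' @param separation expected correlation distance between city templates,
#'   in `[0, 1]`; 1 means independent (orthogonal in expectation).
#' @param attraction_mix lambda in `[0, 1]`: fraction of City 3's template
#'   drawn from the mean of the City 1 and 2 templates.
#' @param seed integer seed; generation is deterministic given the seed.
#' @return An object of class `city_templates`: a list with `templates`
#'   (an `n_voxels` x 4 matrix, one unit-norm column per city), `n_voxels`,
#'   `separation`, `attraction_mix` and `seed`.
#' @examples
#' tpl <- make_city_templates(200, seed = 1)
#' round(cor(tpl$templates), 2)
#' @export
make_city_templates <- function(n_voxels, separation = 1, attraction_mix = 0,
                                seed = 1L) {
  if (!is.numeric(n_voxels) || length(n_voxels) != 1L || n_voxels < 2)
    stop("`n_voxels` must be a single integer >= 2")
  n_voxels <- as.integer(n_voxels)
  stopifnot_scalar_(separation, "separation", 0, 1)
  stopifnot_scalar_(attraction_mix, "attraction_mix", 0, 1)

  templates <- with_seed_(seed, {
    rho <- 1 - separation          # target between-template correlation
    shared <- unit_(stats::rnorm(n_voxels))
    raw <- vapply(seq_len(4L), function(i) {
      sqrt(rho) * shared + sqrt(1 - rho) * unit_(stats::rnorm(n_voxels))
    }, numeric(n_voxels))
    if (attraction_mix > 0) {
      attractor <- unit_((raw[, 1L] + raw[, 2L]) / 2)
      raw[, 3L] <- attraction_mix * attractor +
        (1 - attraction_mix) * raw[, 3L]
    }
    apply(raw, 2L, unit_)
  })
  colnames(templates) <- paste0("city", 1:4)

  structure(
    list(templates = templates, n_voxels = n_voxels, separation = separation,
         attraction_mix = attraction_mix, seed = as.integer(seed)),
    class = "city_templates"
  )
}

#' @export
print.city_templates <- function(x, ...) {
  cat(sprintf("city_templates: 4 templates x %d voxels\n", x$n_voxels))
  cat(sprintf("  separation = %g, attraction_mix (lambda) = %g, seed = %d\n",
              x$separation, x$attraction_mix, x$seed))
  r <- stats::cor(x$templates)
  cat("  pairwise template correlations:\n")
  print(round(r, 3))
  invisible(x)
}
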