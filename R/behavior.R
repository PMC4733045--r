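#' Score retrieval accuracy per city
#'
#' Proportion of correct distance judgements per city, pooling a city's
#' two retrieval blocks. Invariant to trial order.
#'
#' @param log data.frame with at least `city` (1..4) and `correct`
#'   (logical) -- e.g. the `meta` of a [pattern_dataset()] or a response
#'   log read from TSV.
#' @return named numeric vector of per-city accuracies.
#' @export
score_retrieval <- function(log) {
  if (nrow(log) == 0L) stop("empty response log")
  if (!all(log$city %in% 1:4))
    stop("unknown city codes: ",
         paste(setdiff(unique(log$city), 1:4), collapse = ", "))
  acc <- tapply(as.logical(log$correct), factor(log$city, levels = 1:4), mean)
  stats::setNames(as.numeric(acc), paste0("city", 1:4))
}

#' Analytic strategy bounds for the swapped-city design
#'
#' Cities 1 and 2 are identical apart from two swapped store locations,
#' and the trial set over-represents the swapped stores: with `n_flipped`
#' of `n_trials` trials having a different correct response in the two
#' cities, a subject answering City 2 purely from City 1 knowledge scores
#' at most `(n_trials - n_flipped) / n_trials`, and a subject who answers
#' the shared-response trials correctly but guesses on the flipped ones
#' expects `(n_trials - n_flipped + n_flipped / 2) / n_trials`. In the
#' scanned design (`n_trials = 20`, `n_flipped = 9`) these bounds are 55%
#' and 77.5%; observed accuracy above them rules out a transfer-only
#' strategy. Exact rational arithmetic; the two bounds always differ by
#' `n_flipped / (2 n_trials)`.
#'
#' @param n_trials trials per block (>= 0).
#' @param n_flipped trials whose correct response differs between the two
#'   cities (`0 <= n_flipped <= n_trials`).
#' @return list with `max_transfer_accuracy` and
#'   `guess_strategy_accuracy`, both proportions.
#' @export
swap_strategy_bounds <- function(n_trials, n_flipped) {
  if (n_trials < 0 || n_flipped < 0) stop("counts must be nonnegative")
  if (n_flipped > n_trials) stop("`n_flipped` cannot exceed `n_trials`")
  if (n_trials == 0) stop("`n_trials` must be positive")
  list(max_transfer_accuracy = (n_trials - n_flipped) / n_trials,
       guess_strategy_accuracy = (n_trials - n_flipped + n_flipped / 2) / n_trials)
}

#' Map-drawing transition costs between cities
#'
#' Signed change in map-drawing score at each city-to-city transition
#' during learning: first drawn map of the new city minus the last drawn
#' map of the previous city. Negative values are learning costs --
#' e.g. interference when switching into a city whose stores conflict
#' with the one just learned.
#'
#' @param scores data.frame with `city` (in encounter order), `round`
#'   (1-based round within city) and `score` (already-computed 0-1 map
#'   accuracy).
#' @return data.frame with one row per transition: `from`, `to`, `cost`.
#' @export
map_transition_cost <- function(scores) {
  cities <- unique(scores$city)
  if (length(cities) < 2L) stop("need at least one completed city transition")
  out <- list()
  for (k in 2:length(cities)) {
    prev <- scores[scores$city == cities[k - 1L], ]
    new <- scores[scores$city == cities[k], ]
    if (!nrow(prev) || !nrow(new)) stop("missing rounds for a transition")
    last_prev <- prev$score[which.max(prev$round)]
    first_new <- new$score[which.min(new$round)]
    out[[k - 1L]] <- data.frame(from = cities[k - 1L], to = cities[k],
                                cost = first_new - last_prev)
  }
  do.call(rbind, out)
}

#' Learning slope of map-drawing scores
#'
#' Ordinary least-squares slope of map score on round index -- the
#' per-round improvement in drawn-map accuracy for one city.
#'
#' @param scores numeric vector of per-round scores (>= 3 rounds).
#' @return scalar slope.
#' @export
learning_slope <- function(scores) {
  if (length(scores) < 3L) stop("need at least 3 rounds for a slope")
  rounds <- seq_along(scores)
  unname(stats::coef(stats::lm(scores ~ rounds))[2L])
}
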