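#' Build an event table for the retrieval runs
#'
#' Turns trial metadata into per-run timing: one scanner run per retrieval
#' block (city x half, 8 runs in the default design), trials at a fixed
#' stimulus-onset asynchrony within each run. Onsets are strictly
#' increasing within a run and durations positive, which downstream
#' estimation relies on.
#'
#' @param meta trial metadata from [make_trial_meta()] (or the `meta` of a
#'   `pattern_dataset`).
#' @param soa stimulus-onset asynchrony in seconds (default 9 s).
#' @param duration trial duration in seconds (default 4 s, the approximate
#'   mean response time of the task).
#' @param start time of the first onset in each run, seconds.
#' @param jitter half-width (seconds) of uniform onset jitter added to
#'   each SOA. A strictly periodic design makes the interior columns of a
#'   finite-impulse-response model linearly dependent, so deconvolution
#'   designs should be jittered; `jitter` must stay below `soa / 2`.
#' @param seed seed for the jitter draws.
#' @return data.frame: `onset`, `duration`, `run`, plus all metadata
#'   columns.
#' @export
make_event_table <- function(meta, soa = 9, duration = 4, start = 6,
                             jitter = 0, seed = 1L) {
  if (duration <= 0) stop("`duration` must be positive")
  if (soa <= 0) stop("`soa` must be positive")
  if (jitter < 0 || jitter >= soa / 2)
    stop("`jitter` must lie in [0, soa / 2)")
  run_key <- paste(meta$city, meta$block_half, sep = "")
  runs <- match(run_key, sort(unique(run_key)))
  onset <- numeric(nrow(meta))
  with_seed_(seed, {
    for (r in unique(runs)) {
      idx <- which(runs == r)
      o <- start + (seq_along(idx) - 1) * soa
      if (jitter > 0)
        o <- o + stats::runif(length(idx), -jitter, jitter)
      onset[idx] <- o
    }
  })
  cbind(data.frame(onset = onset, duration = duration, run = runs), meta)
}

#' Write / read BIDS-style event tables
#'
#' Events are stored as tab-separated text with one row per trial and the
#' column order `onset`, `duration`, then design metadata, following the
#' BIDS events convention.
#'
#' @param events event data.frame from [make_event_table()].
#' @param path file path to a `.tsv`.
#' @return `read_events_tsv` returns the events data.frame.
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "n/a")
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  ev <- utils::read.table(path, header = TRUE, sep = "\t",
                          na.strings = "n/a", stringsAsFactors = FALSE)
  if (!all(c("onset", "duration") %in% names(ev)))
    stop("event table must have `onset` and `duration` columns")
  ev
}
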