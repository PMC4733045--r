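#' Pipeline configuration
#'
#' A validated, serialisable bundle of every parameter the end-to-end
#' synthetic analysis needs: design counts, generator settings, classifier
#' spec, permutation counts and seed. The object is a flat named list, so
#' it round-trips losslessly through JSON.
#'
#' @param n_subjects cohort size.
#' @param n_voxels voxels per subject.
#' @param trials_per_block trials per retrieval block (default 20; the
#'   design fixes 4 cities x 2 blocks).
#' @param noise_sd,p_attract_min,p_attract_max,c3_instability,c3_noise_scale,lapse
#'   generator settings (see [simulate_cohort()]).
#' @param classifier `"logistic"` or `"mlp"`.
#' @param balanced balance training trials across cities?
#' @param decode_voxels voxels per decoding neighbourhood (default 31,
#'   the searchlight size).
#' @param decode_blocks number of disjoint decoding neighbourhoods whose
#'   accuracies are averaged per subject (default 5), emulating the mean
#'   accuracy over a searchlight cluster.
#' @param n_perm cluster permutations.
#' @param bootstrap_iter bootstrap iterations for the FWE t threshold.
#' @param seed integer seed (explicit; no hidden randomness).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_subjects = 19L, n_voxels = 500L,
                            trials_per_block = 20L, noise_sd = 0.15,
                            p_attract_min = 0.15, p_attract_max = 0.65,
                            c3_instability = 0.7, c3_noise_scale = 1.5,
                            lapse = 0.08, classifier = "logistic",
                            balanced = FALSE, decode_voxels = 31L,
                            decode_blocks = 5L, n_perm = 200L,
                            bootstrap_iter = 2000L, seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_voxels = as.integer(n_voxels),
              trials_per_block = as.integer(trials_per_block),
              noise_sd = noise_sd, p_attract_min = p_attract_min,
              p_attract_max = p_attract_max,
              c3_instability = c3_instability,
              c3_noise_scale = c3_noise_scale, lapse = lapse,
              classifier = classifier, balanced = isTRUE(balanced),
              decode_voxels = as.integer(decode_voxels),
              decode_blocks = as.integer(decode_blocks),
              n_perm = as.integer(n_perm),
              bootstrap_iter = as.integer(bootstrap_iter),
              seed = as.integer(seed))
  validate_config_(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config_ <- function(cfg) {
  positive <- c("n_subjects", "n_voxels", "trials_per_block", "n_perm",
                "bootstrap_iter", "decode_voxels", "decode_blocks")
  for (f in positive) {
    if (is.null(cfg[[f]]) || !is.finite(cfg[[f]]) || cfg[[f]] < 1)
      stop(sprintf("config field `%s` must be a positive count", f))
  }
  if (cfg$n_subjects < 2) stop("config: need at least 2 subjects")
  if (is.null(cfg$seed) || is.na(cfg$seed)) stop("config: seed must be explicit")
  if (!cfg$classifier %in% c("logistic", "mlp"))
    stop("config: classifier must be \"logistic\" or \"mlp\"")
  if (cfg$p_attract_min > cfg$p_attract_max)
    stop("config: p_attract range is degenerate")
  invisible(cfg)
}

#' Serialise / restore a pipeline configuration
#' @param cfg a [pipeline_config()].
#' @param path `.json` path.
#' @return `read_config` returns the `pipeline_config`.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, cfg)
}

config_hash_ <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_config(cfg, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full synthetic analysis pipeline
#'
#' Executes the stages in dependency order on one simulated cohort:
#' simulate -> per-subject environment decoding -> misclassification and
#' brain-behaviour coupling -> pattern-similarity matrices, remapping
#' indices and their family-wise-corrected significance -> interference
#' analysis -> behavioural scoring and analytic strategy bounds. All
#' stages are seeded from the config, so a rerun with the same config is
#' identical; the config hash is recorded in the report (and in every
#' file written).
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, per-stage tables are
#'   written as TSV/JSON.
#' @return a `pipeline_report` list; see the elements written by the
#'   stages (`decoding`, `correlation`, `remapping`, `interference`,
#'   `behavior`, `config_hash`).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  validate_config_(config)
  hash <- config_hash_(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage `%s` failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  cohort <- stage("simulate", simulate_cohort(
    n_subjects = config$n_subjects,
    p_attract_range = c(config$p_attract_min, config$p_attract_max),
    n_voxels = config$n_voxels, noise_sd = config$noise_sd,
    c3_instability = config$c3_instability,
    c3_noise_scale = config$c3_noise_scale, lapse = config$lapse,
    n_trials_per_half = config$trials_per_block, seed = config$seed))

  decoding <- stage("decode", {
    # decode at searchlight scale: disjoint `decode_voxels`-sized
    # neighbourhoods, accuracies averaged per subject
    nb <- min(config$decode_blocks,
              config$n_voxels %/% config$decode_voxels)
    if (nb < 1L) stop("`decode_voxels` exceeds `n_voxels`")
    per_subject <- lapply(seq_along(cohort), function(s) {
      res <- lapply(seq_len(nb), function(k) {
        vox <- ((k - 1L) * config$decode_voxels + 1L):
          (k * config$decode_voxels)
        classify_patterns(cohort[[s]]$patterns, voxels = vox,
                          model = config$classifier,
                          balanced = config$balanced,
                          seed = config$seed + 100L * s + k)
      })
      confusion <- Reduce(`+`, lapply(res, `[[`, "confusion"))
      list(per_city_accuracy =
             colMeans(t(vapply(res, `[[`, numeric(4), "per_city_accuracy"))),
           overall_accuracy =
             mean(vapply(res, `[[`, numeric(1), "overall_accuracy")),
           confusion = confusion)
    })
    acc <- t(vapply(per_subject, `[[`, numeric(4), "per_city_accuracy"))
    colnames(acc) <- paste0("city", 1:4)
    confusion <- Reduce(`+`, lapply(per_subject, `[[`, "confusion"))
    mis <- vapply(per_subject, function(r)
      misclassification_rate(r$confusion, 3L, c(1L, 2L)), numeric(1))
    list(per_city_accuracy = acc, pooled_confusion = confusion,
         c3_labeled_similar = mis,
         overall_accuracy = vapply(per_subject, `[[`, numeric(1),
                                   "overall_accuracy"))
  })

  correlation <- stage("behavior_coupling", {
    beh3 <- vapply(cohort, function(s) s$behavior[["city3"]], numeric(1))
    behavior_classifier_correlation(beh3, decoding$per_city_accuracy[, 3])
  })

  remapping <- stage("mps", {
    # subjects must have at least one valid pair in every similarity
    # cell (a heavily attracted subject can lack correct City 3 pairs);
    # others are excluded and counted
    per_subject <- lapply(seq_along(cohort), function(s) {
      tryCatch(remapping_indices(
        similarity_matrix(cohort[[s]]$patterns, seq_len(config$n_voxels))),
        error = function(e) NULL)
    })
    keep <- !vapply(per_subject, is.null, logical(1))
    if (sum(keep) < 3L)
      stop("fewer than 3 subjects with complete similarity matrices")
    idx <- do.call(rbind, per_subject[keep])
    colnames(idx) <- paste0("city", 1:4)
    thr <- bootstrap_fwe_tthreshold(t(idx), n_iter = config$bootstrap_iter,
                                    seed = config$seed)
    tstats <- apply(idx, 2L, function(v)
      mean(v) / (stats::sd(v) / sqrt(length(v))))
    list(indices = idx, mean_index = colMeans(idx), t = tstats,
         fwe_t_threshold = as.numeric(thr),
         significant = tstats > as.numeric(thr),
         n_subjects_used = sum(keep),
         n_subjects_excluded = sum(!keep))
  })

  interference <- stage("interference", {
    per_subject <- lapply(seq_along(cohort), function(s) {
      tryCatch(interference_trial_analysis(
        cohort[[s]]$patterns, seq_len(config$n_voxels))$means,
        error = function(e) NULL)
    })
    keep <- !vapply(per_subject, is.null, logical(1))
    if (sum(keep) < 3L)
      stop("fewer than 3 subjects with all interference conditions")
    cm <- do.call(rbind, per_subject[keep])
    list(cond_means = cm, group = interference_group_test(cm),
         n_subjects_used = sum(keep))
  })

  behavior <- stage("behavior", {
    acc <- t(vapply(cohort, `[[`, numeric(4), "behavior"))
    list(mean_accuracy = colMeans(acc), per_subject = acc,
         swap_bounds = swap_strategy_bounds(20L, 9L))
  })

  report <- structure(list(decoding = decoding, correlation = correlation,
                           remapping = remapping,
                           interference = interference,
                           behavior = behavior, config = config,
                           config_hash = hash),
                      class = "pipeline_report")
  if (!is.null(out_dir)) write_report_(report, out_dir)
  report
}

write_report_ <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) {
    utils::write.table(cbind(x, config_hash = report$config_hash),
                       file.path(out_dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  w(report$decoding$per_city_accuracy, "decoding_accuracy.tsv")
  w(report$remapping$indices, "remapping_indices.tsv")
  w(report$interference$cond_means, "interference_means.tsv")
  w(report$behavior$per_subject, "behavior_accuracy.tsv")
  summary <- list(
    config_hash = report$config_hash,
    mean_city_accuracy = colMeans(report$decoding$per_city_accuracy),
    c3_labeled_similar = mean(report$decoding$c3_labeled_similar),
    behavior_decoding_r = report$correlation$r,
    mean_remapping_index = report$remapping$mean_index,
    remapping_significant = report$remapping$significant,
    interference_cond_means = colMeans(report$interference$cond_means),
    swap_bounds = report$behavior$swap_bounds)
  jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  write_config(report$config, file.path(out_dir, "config.json"))
  invisible(out_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report (config ", substr(x$config_hash, 1, 8), ")\n", sep = "")
  cat("  mean decoding accuracy per city: ",
      paste(sprintf("%.3f", colMeans(x$decoding$per_city_accuracy)),
            collapse = " "), "\n")
  cat(sprintf("  City 3 trials labelled City 1/2: %.3f\n",
              mean(x$decoding$c3_labeled_similar)))
  cat(sprintf("  behaviour-decoding correlation (City 3): r = %.3f, p = %.3g\n",
              x$correlation$r, x$correlation$p))
  cat("  mean remapping index: ",
      paste(sprintf("%.3f", x$remapping$mean_index), collapse = " "), "\n")
  invisible(x)
}
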