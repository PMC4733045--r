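#!/usr/bin/env Rscript
# Stage 3 -- searchlight environment decoding with cluster correction.
#
# Simulates a small cohort whose city-specific signal lives only inside a
# labelled ROI block, runs the 31-voxel ellipsoid searchlight over the
# whole grid for every subject, and submits the per-subject accuracy maps
# to a group one-sample t-map with max-cluster-size permutation
# correction. The surviving cluster should be the ROI block -- the
# synthetic analogue of an information map localising environment codes.

suppressPackageStartupMessages(library(remapkit))
dir.create("results", showWarnings = FALSE)

geo <- make_default_geometry(dims = c(8L, 8L, 6L), roi_corner = c(2L, 2L, 1L),
                             roi_dims = c(4L, 4L, 3L))
nv <- prod(geo$dims)
roi <- which(geo$roi_labels == 2L)
n_sub <- 6

roi_template_set <- function(seed) {
  tpl <- make_city_templates(nv, seed = seed)
  tpl$templates[-roi, ] <- 0                     # signal only inside ROI
  tpl$templates <- apply(tpl$templates, 2, function(v) v / sqrt(sum(v^2)))
  tpl
}

nbs <- make_neighborhoods(geo$mask)
cat(sprintf("searchlight: %d centres, interior neighbourhood size %d\n",
            length(nbs), max(lengths(lapply(nbs, `[[`, "members")))))

maps <- matrix(NA_real_, n_sub, nv)
for (s in seq_len(n_sub)) {
  ds <- simulate_trial_patterns(roi_template_set(10 + s),
                                n_trials_per_half = 20, noise_sd = 0.06,
                                p_attract = 0.4, c3_instability = 0.7,
                                c3_noise_scale = 1.5, seed = 20 + s,
                                geometry = geo)
  sl <- run_searchlight(ds, nbs, seed = s)
  maps[s, sl$centers] <- sl$accuracy
  cat(sprintf("  subject %d: mean accuracy %.3f (in-ROI %.3f)\n", s,
              mean(sl$accuracy), mean(sl$accuracy[sl$centers %in% roi])))
}

rep_ <- max_cluster_permutation(maps, geo$dims, chance = 0.25,
                                n_perm = 200, seed = 99)
print(rep_)
surv <- rep_$clusters[vapply(rep_$clusters, `[[`, logical(1), "survives")]
if (length(surv)) {
  overlap <- length(intersect(surv[[1]]$voxels, roi)) / length(roi)
  cat(sprintf("largest surviving cluster: %d voxels, %.0f%% of the ROI\n",
              surv[[1]]$size, 100 * overlap))
}

cluster_tab <- do.call(rbind, lapply(rep_$clusters, function(cl)
  data.frame(size = cl$size, peak_t = cl$peak, p_corrected = cl$p_corrected,
             survives = cl$survives)))
write.table(cluster_tab, "results/03_clusters.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(voxel = seq_len(nv),
                       mean_accuracy = colMeans(maps),
                       in_roi = seq_len(nv) %in% roi),
            "results/03_accuracy_map.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("decoding information is confined to (and recovered within) the ROI.\n")
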