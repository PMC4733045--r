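# Shared fixture builders: everything is generated in code at test time.

# Small clean dataset: separable templates, optional noise/attraction.
quick_dataset <- function(n_voxels = 60, noise_sd = 0, p_attract = 0,
                          n_trials_per_half = 5, seed = 1, ...) {
  tpl <- make_city_templates(n_voxels, seed = seed)
  simulate_trial_patterns(tpl, n_trials_per_half = n_trials_per_half,
                          noise_sd = noise_sd, p_attract = p_attract,
                          seed = seed + 1000, ...)
}

# A hand-built confusion table (rows = true city).
confusion_of <- function(rows) {
  m <- matrix(as.integer(rows), 4, 4, byrow = TRUE,
              dimnames = list(true = paste0("city", 1:4),
                              pred = paste0("city", 1:4)))
  m
}

# Independent pair-level similarity oracle: mean Fisher z over explicit
# index pairs, written without the package's mps() internals.
naive_mean_z <- function(mat, voxels, pairs) {
  r <- mapply(function(i, j) cor(mat[i, voxels], mat[j, voxels]),
              pairs$i, pairs$j)
  r <- pmin(pmax(r, -1 + 1e-7), 1 - 1e-7)
  mean(atanh(r))
}
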