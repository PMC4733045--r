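Package: remapkit
Title: Multivoxel Pattern Analysis of Environment-Specific Hippocampal Codes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying hippocampal remapping with functional MRI
    multivoxel pattern analysis in a four-environment retrieval design:
    single-trial pattern estimation (finite impulse response deconvolution,
    empirical haemodynamic response extraction, per-trial GLM betas),
    searchlight cross-validated environment decoding with permutation
    cluster correction, trial-matched multivariate pattern similarity with
    a remapping index, interference (incorrect-trial attraction) analysis,
    behavioural scoring with analytic chance bounds for a swapped-store
    design, and a synthetic-data generator that emulates the full design so
    every stage is testable without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    nnet,
    RNifti,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
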