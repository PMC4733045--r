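# remapkit

Multivoxel pattern analysis of environment-specific hippocampal codes, as
a tested, reusable R pipeline.

`remapkit` is for researchers studying spatial **remapping** with fMRI:
whether the hippocampus holds distinct voxel-pattern codes for different
spatial environments, and what happens to those codes when environments
interfere. It implements the complete analysis chain for a four-city
retrieval design — two nearly identical "similar" cities, an
"interference" city that reuses their landmarks in a novel layout, and a
"distinct" city — together with a synthetic-data generator that emulates
the design, so the whole pipeline runs and is validated without any
scanner data.

## What it computes

* **Single-trial patterns** — finite impulse response (FIR)
  deconvolution, empirical HRF extraction by logistic infomax ICA (first
  principal component as cross-check), cubic-spline resampling to
  microtime, and a per-trial GLM giving a trials × voxels beta matrix
  (`fit_fir()`, `extract_empirical_hrf()`, `resample_hrf()`,
  `estimate_single_trial_betas()`).
* **Searchlight decoding** — 31-voxel ellipsoid neighbourhoods, split-half
  cross-validation over retrieval blocks (train on correct trials of one
  half, test all of the other, swap), 4-way multinomial logistic
  classification, per-city accuracies and 4 × 4 confusion structure,
  with a balanced-training variant (`make_neighborhoods()`,
  `classify_patterns()`, `run_searchlight()`,
  `misclassification_rate()`).
* **Multivariate pattern similarity (MPS)** — trial-matched Pearson
  correlations, Fisher z per pair, and the **remapping index**

  $$\mathrm{RI}(c) \;=\; \bar z_{\,c\,\text{within}} \;-\;
  \tfrac{1}{3}\textstyle\sum_{c' \ne c} \bar z_{\,c,c'} ,$$

  positive when a city's code is reinstated for itself and separated
  from its competitors (`similarity_matrix()`, `remapping_index()`),
  plus the incorrect-trial interference contrast
  (`interference_trial_analysis()`) and a univariate activation control.
* **Group inference** — one-sample t-maps against chance, connected
  clusters, max-cluster-size sign-flip permutation correction, and the
  bootstrap max-|t| family-wise threshold used by the MPS tests
  (`one_sample_tmap()`, `max_cluster_permutation()`,
  `bootstrap_fwe_tthreshold()`).
* **Behaviour** — per-city retrieval scoring, the analytic strategy
  bounds of the swapped-store design (a transfer-only strategy caps at
  55%, answer-shared-and-guess at 77.5%, for 9 response-flipped trials
  of 20), and map-drawing learning metrics (`score_retrieval()`,
  `swap_strategy_bounds()`, `map_transition_cost()`,
  `learning_slope()`).

The numbered scripts under `analysis/` run these stages as a narrative
workflow (simulate → estimate → searchlight → inference calibration →
MPS → behaviour), writing their tables under `results/`. The methods
vignette (`vignettes/remapping-analysis.Rmd`) documents the generative
model, every tunable parameter, and the numerical design choices.

## Worked example

Run the full synthetic analysis at the reference study conditions
(19 subjects, City 3 attraction centred on 0.4):

```r
library(remapkit)
report <- run_pipeline(pipeline_config(seed = 1))
print(report)
#> pipeline_report (config a15f61f9)
#>   mean decoding accuracy per city:  0.523 0.580 0.192 0.590
#>   City 3 trials labelled City 1/2: 0.616
#>   behaviour-decoding correlation (City 3): r = 0.930, p = 8.49e-09
#>   mean remapping index:  0.071 0.073 0.011 0.081
```

Reading those numbers: the similar and distinct cities decode well above
the 4-way chance of 0.25 while the interference city falls *below*
chance, with 62% of its trials labelled as one of the similar cities —
its code is not merely weak but attracted toward its competitors.
Subjects who retrieve City 3 more accurately also decode it better
(r = 0.93 here). The remapping index is clearly positive for Cities 1, 2
and 4 and near zero for City 3; `report$remapping$significant` shows
Cities 1, 2 and 4 clearing the bootstrap family-wise t threshold and
City 3 missing it, and `report$interference$group` shows incorrect
City 3 trials resembling correct City 1/2 patterns more than correct
City 3 trials do.

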