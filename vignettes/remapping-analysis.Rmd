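---
title: "Methods: environment-specific pattern analysis with remapkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: environment-specific pattern analysis with remapkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Rodent place cells "remap": the ensemble code for one spatial environment
reorganises when the animal enters another, and stable reinstatement of the
right map is thought to underlie successful spatial memory. `remapkit`
implements the analysis pipeline needed to ask the analogous question of
human fMRI data in a four-environment retrieval design:

* **Cities 1 and 2** ("similar") share stores and geometry, with two store
  locations swapped;
* **City 3** ("interference") reuses the same stores in a novel layout, so
  its memory competes directly with Cities 1 and 2;
* **City 4** ("distinct") has novel stores and layout.

Subjects retrieve spatial distances from a cued city, two retrieval blocks
("A" and "B" halves) of 20 triad judgements per city. The analysis asks
whether local voxel patterns carry environment identity (searchlight
decoding), whether pattern similarity is higher within than between
environments (the remapping index), and whether interference errors are
accompanied by attraction toward the competing environments' patterns.

Because no scanner data ship with the package, a synthetic generator
reproduces the design's statistical structure end to end; every pipeline
stage is validated against it.

## Generative model

Templates are unit-norm Gaussian voxel vectors, one per city
(`make_city_templates()`). A trial's pattern is its city's template plus
i.i.d. Gaussian noise, so the expected correlation of two trials of the
same city is $1 / (1 + \sigma^2 n_\mathrm{vox})$ — the attenuation law the
tests assert. Two dials create departures from full separation:

* `separation` mixes a shared component into all templates (expected
  between-city template correlation $\approx 1 - \mathrm{separation}$);
* `attraction_mix` ($\lambda$) draws City 3's *template* toward
  $\mathrm{mean}(T_1, T_2)$, with
  $\mathrm{cor}(T_3, \bar T_{12}) = \lambda / \sqrt{\lambda^2 + (1 - \lambda)^2}$.

City 3's failure mode is modelled at the trial level:

* with probability `p_attract` a City 3 trial is generated from the City 1
  or City 2 template outright; it is answered incorrectly and its
  attractor recorded — retrieval pattern-completed to the wrong map;
* correctly answered City 3 trials can still rest on an unstable code:
  with `c3_instability` $= \mu > 0$ their signal is
  $\mathrm{unit}((1-\mu) T_3 + \mu T_a)$, $T_a$ a per-trial uniform draw
  from $\{T_1, T_2\}$, with noise scaled by `c3_noise_scale`.

The second mechanism is essential: with attraction confined to incorrect
trials, correct City 3 trials would carry a clean, fully separated
template, and no analysis could show the empirical signature of
interference — below-chance decoding of City 3, the majority of its trials
labelled City 1/2, and a near-zero City 3 remapping index. Partial
instability of even-correct trials is the minimal mechanism that produces
all three. Both parameters default to off (`0`/`1`), so the plain
generator behaves exactly as its contract states; the cohort generator
switches them on as study conditions.

`simulate_cohort()` couples neural and behavioural data through a single
cause: per-subject `p_attract` is drawn from `p_attract_range`
(default $U(0.15, 0.65)$, mean 0.4), City 3 behavioural accuracy is the
observed proportion of correct trials ($\approx 1 - p_\mathrm{attract}$ at
40 trials), and the instability of correct City 3 trials scales with the
subject's attraction rate, $\mu_i = \min(1,\, 0.7\, p_i / 0.4)$. Subjects
with more stable City 3 codes therefore both answer better and decode
better — the across-subject brain–behaviour coupling the pipeline tests.

### Reference study conditions

| parameter | default | rationale |
|---|---|---|
| `n_voxels` | 500 | a hippocampal-subfield-sized ROI |
| `noise_sd` | 0.15 | within-city trial correlation $\approx 0.08$ and searchlight accuracies in the 0.4–0.6 range, i.e. weak single-trial signal typical of high-resolution fMRI; chosen once when the generator was designed |
| `p_attract_range` | (0.15, 0.65) | mean 0.4; spread creates the behavioural variance the correlation analysis needs |
| `c3_instability` | 0.7 (at $p = 0.4$) | strong-but-partial attraction of correct City 3 trials |
| `c3_noise_scale` | 1.5 | the unstable code is also noisier |
| `lapse` | 0.08 | non-interference errors, so Cities 1/2/4 sit near 90% correct |
| `tr` | 3 s | acquisition repetition time |
| trial `duration` | 4 s | approximate mean response time |

The voxel-level effect sizes have no empirical anchor (the design's
separations are behavioural, not voxelwise), so `noise_sd` and the City 3
instability are calibration choices fixed once for the package's reference
conditions and never tuned per analysis.

What the generator does **not** emulate: spatial autocorrelation and
physiological noise (drift, motion), anatomical subfield geometry,
visual-stimulus structure beyond triad identity, and any scaling of
pattern separation with environment similarity. Passing tests therefore
show the *analysis* behaves correctly under the design's assumed
statistical structure, not that real hippocampal data satisfy those
assumptions.

## Single-trial estimation

The estimation chain mirrors standard practice for pattern analyses,
which need maximally orthogonalised per-trial responses:

1. **FIR deconvolution** (`build_fir_design()`, `fit_fir()`): indicator
   regressors for the 10 scans (30 s at TR 3 s) after each onset. The
   per-trial form is identifiable only in sparse or jittered designs — in
   a dense periodic block (20 trials, 9 s SOA, ~70 scans) it has more
   regressors than scans — so `per_trial = FALSE` estimates one shared
   10-bin response per run, which is the form fed to HRF extraction.
   `make_event_table(jitter = )` provides onset jitter for deconvolution
   designs.
2. **Empirical HRF** (`extract_empirical_hrf()`): logistic infomax ICA
   (natural-gradient Bell–Sejnovski on PCA-whitened profile scores;
   identity initialisation, seeded row shuffles) over the stacked
   run × voxel FIR profiles. ICA components are not variance-ordered, so
   the returned kernel is explicitly the component with the largest
   back-projected variance, sign-aligned to a positive peak;
   `method = "first_pc"` is the deterministic cross-check. The scope of
   the profile stack (one run, one subject, a whole cohort) is the
   caller's choice — the function only sees a profile matrix.
   Note the extracted shape is the *stimulus-locked response* (trial
   boxcar convolved with the underlying HRF); regressors built from it
   should use impulse events.
3. **Spline resampling** (`resample_hrf()`): cubic spline interpolation
   to 16 bins per scan, the conventional microtime resolution. The
   interpolant passes through the original samples exactly. Fidelity to
   the underlying curve depends on the base sampling: a double-gamma
   sampled at 1 s upsamples to within 2% of the closed form, whereas 3 s
   sampling leaves ~18% peak-relative error concentrated in the initial
   rise — an undersampling fact the tests document rather than hide.
4. **Per-trial GLM** (`estimate_single_trial_betas()`): one convolved
   boxcar regressor per trial plus intercept, ordinary least squares per
   run, joint over all trials of the run ("least-squares-all"). Exactly
   collinear trial regressors are a named error rather than silently
   dropped coefficients. No autocorrelation model is fitted — upstream
   band-pass filtering is assumed and out of scope.

## Searchlight decoding

`make_neighborhoods()` builds one ellipsoid neighbourhood per in-mask
voxel. Semi-axes default to (2.2, 2.2, 1.5) voxel units: with the
acquisition's anisotropic 1.6 × 1.6 × 2 mm voxels this is a ~3.5 mm
quasi-sphere, and it is the smallest such ellipsoid containing exactly 31
lattice points at an interior centre. Other `target_size`s are met by
uniform rescaling of the axes.

Cross-validation is the design's natural split (`split_half_folds()`):
train on the A block of every city, test on B, then swap. Only correct
trials train; all trials are scored at test, which is what lets the
interference analyses look at incorrect trials. `balance_training()`
implements the balanced-trials control protocol (equal per-city training
counts by seeded subsampling).

The default classifier is multinomial logistic regression
(`nnet::multinom`). The claims under test concern the information content
of local patterns, not a classifier family, and the backpropagation
network it stands in for is underspecified (layer sizes, training
schedule); a small MLP (`model = "mlp"`) is retained for sensitivity
checks. Fits run under a fixed internal RNG state so results are
reproducible; exact score ties break toward the lowest city index.
Misclassification structure is read from the pooled 4 × 4 confusion
table; `misclassification_rate()` defaults to all source trials in the
denominator (chance 0.5 for two of four labels), with the
misclassified-only variant available.

## Pattern similarity and the remapping index

`mps()` computes, per matched trial pair, the Pearson correlation of the
two trials' patterns over the ROI voxels, Fisher-z transforms each
(`atanh`; the standard choice for averaging correlations — the raw-r
average is available by transforming back), and averages. Pairs at the
$|r| = 1$ boundary (possible in noise-free synthetic data) are clipped to
$1 - 10^{-7}$ and counted; constant patterns are dropped with a warning.

Pair matching (`match_trial_pairs()`) holds the visual stimulus constant
wherever the design permits: within-city cells pair the same triad across
the A and B blocks (which also guarantees opposite motor responses, the
design's button-swap control); between-city cells among Cities 1–3 match
triads the same way, pairing across halves in both directions. City 4 has
a disjoint stimulus set, so its cells use all pairwise combinations of
correct trials; forcing that scheme everywhere
(`similarity_matrix(scheme = "all_pairwise")`) is the control for the
matching rule, and on exchangeable synthetic data the two schemes agree.

The **remapping index** of a city is its within-city mean z minus the
mean of its three between-city z values — positive when the environment's
code is reinstated for itself and separated from its competitors, near
zero when it is not. Per-city significance uses one-tailed one-sample
t-tests against zero at the family-wise threshold from
`bootstrap_fwe_tthreshold()`.

At the cohort level, a subject enters the group similarity analyses only
if every cell of their similarity matrix (and every interference
condition) has at least one valid pair — a heavily attracted subject can
lack correct City 3 triad pairs entirely; excluded subjects are counted
in the pipeline report (`n_subjects_excluded`).

The **interference analysis** (`interference_trial_analysis()`) compares
four triad-matched condition means — incorrect/correct City 3 crossed
with correct City 1/2 (matched) and correct City 4 (all-pairwise) — and
`interference_group_test()` runs the paired two-tailed t-tests of
condition 1 against the rest. `univariate_control()` closes the loop:
mean activation per ROI × city with a repeated-measures ANOVA, showing
multivariate effects are not univariate shifts in disguise.

## Group inference

`one_sample_tmap()` is the voxelwise one-sample t against chance;
zero-variance voxels are masked with a warning. Cluster inference
(`max_cluster_permutation()`) sign-flips each subject's deviation from
chance — the standard exchangeable null for a one-sample test, and the
cheap stand-in for relabel-and-retrain — recomputes the t-map, forms
connected components, and records the maximum cluster size; observed
clusters are reported with permutation p-values
$(1 + \#\{\mathrm{null} \ge s\}) / (n_\mathrm{perm} + 1)$ and survive at
corrected $p < 0.05$.

Numerical choices worth recording:

* **Cluster-forming threshold**: one-tailed Student quantile at
  $\alpha = 0.05$ by default. The hypothesis (above-chance decoding) is
  directional, and on desk-scale grids the discrete max-size null under a
  two-tailed forming threshold is so tie-ridden that the empirical
  family-wise error drops to ~0.02; one-tailed forming keeps it near the
  nominal 0.05. The two-tailed variant remains available.
* **Connectivity**: 18 (faces + edges) by default, configurable to 6/26.
* **Bootstrap FWE** (`bootstrap_fwe_tthreshold()`): per iteration,
  sign-flips are applied per subject jointly across conditions, preserving
  the family's within-subject dependence (a cellwise variant exists); the
  corrected threshold is the 95th percentile of the max-|t| distribution.
  At one condition this reproduces the ordinary t quantile; it grows with
  the family size.

## Problem sizes

The validation suite and the acceptance script run everything at desk
scale, chosen as the package's reference sizes: cohorts of 19 subjects
with 500-voxel patterns; decoding at searchlight scale (five disjoint
31-voxel neighbourhoods averaged per subject — the analogue of averaging
a searchlight map over a cluster); null calibration with 200 label
permutations; family-wise error measured over 200 null replicates with
200 cluster permutations / 2000 bootstrap iterations each. Full-grid
searchlights (the `analysis/03` driver uses an 8 × 8 × 6 grid) scale
linearly in centres.

## Known limitations

* The generator's noise is white in space and time; cluster-level
  inference on real data would additionally face smoothness estimation,
  which is out of scope.
* Preprocessing (slice timing, motion, band-pass) and anatomical
  alignment are assumed done; subject maps enter group inference already
  on a common grid.
* The map-drawing score rubric is not defined here; learning-curve
  helpers consume already-computed 0–1 scores.
* Behavioural coupling in the cohort is one-parameter by design
  (accuracy $= 1 - p_\mathrm{attract}$); it makes the brain–behaviour
  correlation testable but is not a cognitive model of distance
  judgements.
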