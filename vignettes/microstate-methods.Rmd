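---
title: "EEG microstate analysis and Bayesian-optimized classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEG microstate analysis and Bayesian-optimized classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of its methods: the models it
implements, the parameters that matter, what the synthetic cohort
generator does and does not emulate, and the numerical and design
choices that were genuinely open.

## The analysis in one paragraph

Spontaneous EEG, viewed as a sequence of scalp potential topographies,
alternates among a small number of quasi-stable maps ("microstates",
~60–120 ms dwell times), conventionally labeled A–D. The pipeline
implemented here: (i) band-pass filters (2–20 Hz), re-references to the
common average and cuts recordings into 5-s epochs, rejecting epochs
whose overall variance exceeds mean + 3 SD within the subject; (ii)
computes the global field power `GFP(t) = sqrt(sum_i (V_i - Vbar)^2 / N)`
(the spatial standard deviation over the `N` electrodes) and collects
the topographies at its local maxima, the moments of highest topographic
signal-to-noise; (iii) clusters the pooled peak maps with a
polarity-invariant modified K-means into `K = 4` templates and labels
them A–D against canonical reference gradients; (iv) backfits the
templates to every epoch, producing a per-sample state sequence; (v)
derives 20 features — occurrence (Hz), mean duration (ms), coverage
(%), mean GFP (µV) and the mean spatial correlation between a state's
labeled peaks and its template (MsMC, unitless in [0, 1]) for each of
A–D; (vi) ranks the features with chi-square tests on equal-frequency
binned values; and (vii) selects and tunes a classifier from a
nine-family pool by Bayesian optimization (random-forest surrogates,
expected-improvement acquisition, 5-fold cross-validated
misclassification objective), evaluating either a stratified 80/20
epoch split (subject-dependent) or leave-one-subject-out folds.

## Modified K-means and GEV

Peak maps are average-referenced and scaled to unit norm; spatial
similarity is the absolute Pearson correlation across channels, so map
polarity (which alternates with the oscillatory carrier in real EEG) is
ignored throughout. The clustering alternates: (assignment) each peak
joins the template with the largest squared correlation; (update) each
template becomes the principal eigenvector of the outer-product scatter
of its assigned *raw* (average-referenced, unnormalized) maps. Because
that scatter equals the GFP²-weighted scatter of the normalized maps,
both steps are exact coordinate ascent on the global explained variance

    GEV = sum_t (GFP_t * r_t)^2 / sum_t GFP_t^2 ,

where `r_t` is the correlation of peak `t` with its assigned template.
Every converged run therefore sits at a local GEV maximum; on tiny
instances the procedure reproducibly attains the global optimum found
by exhaustive assignment enumeration (this is tested). Convergence is
declared when the relative GEV change drops below `tol` (default 1e-6,
the reference setting) or after `maxIter` (1000) iterations; the best
of `nRestarts` (20) random restarts wins, with restarts drawn from
*distinct* initial peak subsets so small instances get broad basin
coverage. An emptied cluster is re-seeded from the currently
worst-explained peak. The principal eigenvector's sign is fixed
(largest-magnitude component positive) so results are bit-reproducible.

Canonical labeling compares the four learned templates against
constructed reference gradients (A: right-frontal/left-posterior, B:
left-frontal/right-posterior, C: frontal–occipital midline, D: midline
frontal focus) over all 24 permutations, maximizing the summed absolute
correlation; ties break lexicographically.

Backfitting labels each GFP peak by maximal absolute correlation and
fills non-peak samples from the nearest peak, with the boundary at the
midpoint between consecutive peaks. The temporal resolution of this
rule is limited by the peak spacing: with a 10 Hz dominant rhythm,
peaks arrive every ~50 ms, so each state transition is located only to
within ±25 ms. Run-level statistics (occurrence, duration, coverage)
average this blur out, but per-sample label agreement with ground truth
saturates around 90% when dwell times are at the 60 ms scale — the
≥95% agreement property is therefore checked at dwells long relative to
the peak spacing, where boundary blur is provably small. No temporal
smoothing or small-segment rejection is applied.

## Features

All 20 features are computed per retained 5-s epoch (the classification
sample unit); `aggregateBySubject()` provides subject-level means for
cohort-style reporting. Runs truncated by epoch edges count as runs; a
state absent from an epoch contributes 0 to its features and is
recorded in a flags attribute rather than producing NA (keeps the table
dense for classifiers without losing the information). Coverage sums to
100% by construction and satisfies `occurrence × duration / 10 =
coverage` exactly on partition labelings; both identities are tested on
every generated epoch.

## Feature ranking and explanations

Each feature is discretized into `nBins = 10` equal-frequency bins
(tied breakpoints merged; a constant feature collapses to one bin and
scores zero) and tested against the group label with a Pearson
chi-square test without continuity correction. The importance score is
`-log10(p)`, computed on the log scale so that extremely small p-values
remain finite and the ranking stays strict. Equal-frequency binning
makes the ranking invariant to strictly monotone feature transforms.

Shapley explanations use the interventional value function: the value
of a coalition S is the mean model score over background rows with the
query's values substituted on S. Up to 12 features, all 2^d coalitions
are enumerated and the values are exact (local accuracy to machine
precision: contributions sum to the query score minus the mean
background score); beyond that a permutation-sampling estimator is
used.

## Bayesian-optimized classification

The learner pool mirrors the usual automatic-selection families:
discriminant (Gaussian, linear/quadratic covariance with shrinkage
toward the scaled identity), ensemble (bagged trees via ranger, 50–400
trees), kernel (random-Fourier-feature logistic regression, bandwidth
and ridge penalty log-uniform), knn (k in 1..50, log), svm
(linear/radial/polynomial-2,3 kernels, cost and kernel scale log-uniform
1e-3..1e3), linear (ridge logistic), naive Bayes (Gaussian or kernel
density class-conditionals), net (one hidden layer, 4–64 units, weight
decay log-uniform) and tree (minimum leaf size 1–64, log). Features are
standardized on the training split inside the fitting wrapper.

The optimization evaluates a stratified 5-fold cross-validated
misclassification rate. After a round-robin random initialization
(`nInit` configurations per learner, truncated by the budget), each
learner's evaluated points are modeled by a regression random forest —
one surrogate per learner family; the predictive mean and the spread of
per-tree predictions feed the closed-form expected-improvement score of
256 fresh random candidates per learner, and the globally best
candidate is evaluated next. The incumbent (lowest objective in the
trace) is refit on the full training split before testing. All
randomness — fold assignment, candidate draws, surrogate fits,
stochastic learners — is driven by seeds pre-drawn from the master
seed, so a report is exactly reproducible from (table, configuration,
seed).

The subject-dependent protocol splits epochs 80/20 stratified by group,
so epochs of one subject can appear on both sides — the optimistic but
reference design for small cohorts. The leave-one-subject-out variant
holds out one subject per group per fold (`min(n_HC, n_SZ)` folds),
refitting the selected incumbent configuration from scratch on each
fold's training epochs. The configuration itself is selected once on
the full table before the fold loop; this configuration-level
selection sees all subjects (a known, deliberate simplification — the
per-fold *weights* never see the held-out subjects, and at desk scale
re-running the whole search inside every fold would multiply the cost
fourteenfold for no change in the comparison being made). Sensitivity
takes the SZ-like group as the positive class; AUC is the Mann–Whitney
rank statistic of the continuous scores, with decision values used for
margin classifiers.

## The synthetic cohort generator

The generator exists so that every downstream stage is testable against
known ground truth without any data download. It emulates two groups
("HC" and "SZ") of 14 subjects recorded for 15 minutes at 250 Hz on the
19-channel 10/20 montage, with per-state dynamics calibrated to the
reference group statistics: occurrence targets (HC
3.65/4.26/4.13/4.01 Hz, SZ 4.05/4.41/2.34/4.49 Hz for A–D), mean dwell
times (HC 67.2/58.5/55.9/65.1 ms, SZ 56.2/59.5/57.3/79.8 ms), mean GFP
(SZ higher in every state) and topographic consistency (MsMC lower in
SZ for A–C, equal for D). These targets are internally consistent
(occurrence × duration ≈ coverage; total dwell ≈ 1 s/s), which is what
makes them usable as generative parameters.

Mechanism and the choices behind it:

* **State sequence** — a semi-Markov chain: run types drawn from
  occurrence weights with self-transitions forbidden, dwell times gamma
  with the state's mean. Because zeroing the current state's weight
  inflates low-weight states (the SZ C state would run ~14% hot), the
  drawing weights are pre-calibrated by a fixed-point iteration on the
  chain's stationary distribution so realized run frequencies match the
  targets.
* **Dwell dispersion** — gamma shape 8 (CV ≈ 0.35). Real dwell
  distributions are broader; the narrower choice keeps dwells below a
  quarter carrier period (invisible to GFP-peak backfitting at 250 Hz)
  rare, so that the generator's own recovery property — occurrence and
  duration recoverable within 10% through the full pipeline at ~10%
  sensor noise — holds. This is a property the estimator needs, not a
  claim about real EEG.
* **Carrier** — each run is the state's topography times a 10 Hz sine
  rising from zero at the run onset. Transitions therefore sit at GFP
  minima (the empirical behavior of real microstate syntax), every
  dwell beyond a quarter period carries a GFP maximum, the polarity
  alternation matches real alpha, and the signal's energy sits
  mid-passband so the 2–20 Hz filter leaves the topographies intact.
  The GFP at carrier extrema equals the state's amplitude parameter.
* **Amplitudes** — the observed mean-GFP *feature* mixes the generative
  amplitude with dwell-length and boundary-attribution effects (the
  effective attenuation factors, 0.55–0.61, are stable to ±0.002 across
  seeds). Amplitude defaults are therefore set to target ÷ measured
  factor, so the observed features land on the reference values; for
  state D this makes the generative amplitude ordering differ from the
  observed one, which is the point of the calibration.
* **Topographic variability** — each run's map is the template plus
  `topoJitter` times a white average-referenced map, renormalized;
  higher jitter lowers MsMC. Contrasts are set so the standardized MsMC
  group differences stand in the reference proportions to the
  occurrence effect (C strongest, A and B weak, D null). Matching the
  reference's *absolute* MsMC level (~0.6) would require jitter so
  large that peak labeling degrades ~20% and the recovery property
  above becomes unattainable; the defaults put MsMC near 0.88–0.94 and
  preserve all group directions.
* **Noise** — spatially white Gaussian (default 0.8 µV, ~10% of the
  amplitude scale), re-referenced to zero channel mean so every frame
  keeps the average-reference invariant exactly.
* **Templates** — linear/quadratic functions of the schematic scalp
  coordinates realizing the canonical A–D gradients; the midline
  frontal map is partially decorrelated from the others so all pairwise
  absolute correlations stay at or below 0.7 (realized maximum 0.63)
  while its maximum stays fronto-central.

What the generator does *not* emulate: volume conduction and realistic
forward-model leakage, ocular/muscle artifacts, between-subject
parameter heterogeneity (all subjects of a group share one parameter
set, so between-subject variance is purely sampling), non-stationarity
across the recording, and broadband background EEG. Consequently the
synthetic cohorts are *cleaner* than real data: classification
accuracies near 100% on them demonstrate that the pipeline wiring is
correct and leak-free, not that real cohorts are separable at that
level, and leave-one-subject-out agrees with the subject-dependent
protocol more tightly than it would on real recordings.

## Problem sizes used in the shipped checks

The shipped validation uses desk-scale study sizes chosen to keep every
property measurable with margin: the recovery study uses 4 subjects per
group × 60 s (≈ 9,000–11,000 pooled peaks); the classification cohort
uses the full 14 + 14 subjects at 60 s each (336 epochs), a
24-evaluation optimization budget and the top-6 ranked features; the
clustering-oracle check uses ≤ 8 peak maps so the 2^8 assignment
enumeration is exact. The acceptance script
(`scripts/acceptance.R`) re-runs both studies from scratch at any seed.

## Known limitations

* Backfit boundary placement is quantized by the GFP peak spacing;
  per-sample agreement (not run statistics) degrades as dwell times
  approach the carrier half-period.
* The chi-square ranking treats epochs as independent; epochs of one
  subject are correlated, so the importance scores are optimistic in
  absolute terms (their ordering is what the pipeline uses).
* The LOSO protocol reuses the configuration selected on the full
  table (see above); metrics remain honest per fold, but configuration
  selection is not nested.
* Exact Shapley values are exponential in the feature count; beyond 12
  features the sampling estimator introduces Monte-Carlo error.
* The EDF writer/reader covers continuous 16-bit single-rate
  recordings (the common case), not the full EDF+ annotation layer.
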