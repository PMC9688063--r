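# microstates

Resting-state EEG **microstate** analysis and Bayesian-optimized
classification, in R.

Spontaneous EEG, viewed as a sequence of scalp potential topographies,
alternates among a handful of quasi-stable maps (~60–120 ms), the
microstate classes A–D. Altered microstate dynamics are a candidate
neurophysiological marker in schizophrenia research, and the usual
analysis chain — segmentation into microstates, per-state features,
feature ranking, multivariate classification — involves enough moving
parts that a tested, reproducible implementation is worth having. This
package provides that chain end to end for methodologists and EEG
researchers, together with a seeded synthetic-cohort generator with
known ground truth so that every stage can be validated without any
data download.

## What it computes

* **Global field power**, the spatial standard deviation over the `N`
  electrodes: `GFP(t) = sqrt( Σᵢ (Vᵢ(t) − V̄(t))² / N )`. Its local
  maxima are the moments of highest topographic signal-to-noise and the
  substrate of everything downstream.
* **Polarity-invariant modified K-means** over GFP-peak topographies:
  peaks are assigned by maximal squared spatial correlation and
  templates updated as principal eigenvectors of the assigned maps'
  scatter, which makes the alternation exact coordinate ascent on the
  **global explained variance**
  `GEV = Σₜ (GFPₜ·rₜ)² / Σₜ GFPₜ²` (20 restarts, tolerance 1e-6, max
  1000 iterations by default). Templates are labeled A–D against
  canonical reference gradients, then **backfit** to every epoch by a
  nearest-peak midpoint rule.
* **20 microstate features** per 5-s epoch: occurrence (Hz), mean
  duration (ms), coverage (%), mean GFP (µV) and **MsMC** — the mean
  absolute spatial correlation between a state's labeled peaks and its
  template — for each of A–D.
* **Chi-square feature ranking** (equal-frequency bins, importance
  `−log₁₀ p`), pooled-variance group t-tests with Bonferroni flags, and
  **exact interventional Shapley values** for model explanation.
* **Bayesian-optimized classifier selection** over nine learner
  families (discriminant, ensemble, kernel, knn, svm, linear, naive
  Bayes, neural net, tree): random-forest surrogate per family,
  expected-improvement acquisition, 5-fold cross-validated
  misclassification objective, evaluated on a stratified 80/20 epoch
  split or leave-one-subject-out folds (accuracy, AUC, sensitivity,
  specificity).

Recordings are read/written as plain CSV (with a JSON sidecar) or
16-bit EDF. See `vignette("microstate-methods")` for the models,
assumptions and design choices.

## Worked example

```r
library(microstates)

## simulate a small two-group cohort (4 subjects/group, 60 s each)
cfg <- generatorConfig(nPerGroup = 4, duration = 60, seed = 42)
cohort <- generateCohort(cfg)
cohort$recordings[[1]]
#> EEGRecording 'HC01' [HC]: 19 channels x 15000 samples @ 250 Hz (60.0 s)

## preprocess: 2-20 Hz band-pass, average reference, 5-s epochs,
## variance-based epoch rejection
epochs <- lapply(cohort$recordings, function(r)
  rejectOutlierEpochs(epochSignal(averageReference(bandpassFilter(r)), 5)))

## pool GFP-peak maps across subjects and cluster into 4 microstates
peaks <- lapply(epochs, extractPeakMaps)
pooled <- new("PeakSet",
              indices = seq_along(unlist(lapply(peaks, peakGFP))),
              maps = do.call(cbind, lapply(peaks, peakMaps)),
              gfp = unlist(lapply(peaks, peakGFP)))
km <- modifiedKMeans(pooled, K = 4, nRestarts = 20, seed = 42)
templates <- assignCanonicalLabels(km$templates,
                                   makeTemplates(standardMontage1020()))
templates
#> TemplateSet: 4 maps (A, B, C, D) over 19 channels; GEV = 0.878

## how well were the ground-truth maps recovered?
round(diag(abs(cor(templateMaps(cfg$templates), templateMaps(templates)))), 3)
#>     A     B     C     D
#> 0.997 0.998 0.994 1.000

## extract the 20 microstate features per epoch and rank them
feats <- extractFeatureTable(epochs, templates)
ranking <- chi2RankFeatures(feats, nBins = 10)
head(ranking[, c("feature", "importance")], 4)
#>        feature importance
#> 1   Duration_D   12.04277
#> 2 Occurrence_C   11.77372
#> 3   Coverage_D   11.28860
#> 4   Coverage_C   10.18280

## Bayesian-optimized classification on the top-4 ranked features
report <- evaluateHoldout(feats, ranking$feature[1:4], budget = 12,
                          nInit = 1, seed = 42)
report
#> ClassificationReport [subject_dependent]
#>   accuracy 100.00%  AUC 1.000  sensitivity 100.00%  specificity 100.00%
#>   best learner: discriminant (type=linear, gamma=0.461)
#>   features (4): Duration_D, Occurrence_C, Coverage_D, Coverage_C
```

Reading the output: the four clustered templates explain 87.8% of the
GFP-weighted topographic variance at the peaks and match the
ground-truth maps at |r| ≥ 0.994; the top-ranked features are the C- and
D-state dynamics, whose group contrasts the generator encodes; and the
held-out 20% of epochs is classified perfectly — the synthetic cohort
is deliberately cleaner than real EEG (no artifacts, no between-subject
heterogeneity), so this demonstrates correct, leak-free wiring rather
than real-data separability.

A full pipeline run with artifacts on disk is one call
(`runPipeline(pipelineConfig(...), "out_dir")`), and
`inst/scripts/run_pipeline.R` wraps it for the shell.

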