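#' Ground-truth microstate template maps
#'
#' Builds four average-referenced, unit-norm topographies realizing the
#' canonical qualitative gradients of the resting-state microstate classes:
#' A (right-frontal / left-posterior), B (left-frontal / right-posterior),
#' C (frontal-occipital midline gradient) and D (midline frontal focus).
#' Maps are linear/quadratic functions of the scalp coordinates; D is
#' partially decorrelated from the others so that every pairwise absolute
#' spatial correlation stays at or below 0.7. The construction is
#' deterministic; `seed` is recorded in the returned object.
#'
#' @param montage a [Montage-class] with at least 4 channels at distinct
#'   positions.
#' @param seed integer recorded as template-set metadata.
#' @return A [TemplateSet-class] with labels `A`, `B`, `C`, `D`.
#' @examples
#' tpl <- makeTemplates(standardMontage1020())
#' round(crossprod(templateMaps(tpl)), 2)
#' @export
makeTemplates <- function(montage, seed = 1L) {
  if (length(montage@channels) < 4L)
    stop("montage must have at least 4 channels")
  if (anyDuplicated(montage@positions, MARGIN = 1))
    stop("montage must have 4 channels with distinct positions")
  x <- montage@positions[, 1]
  y <- montage@positions[, 2]
  nrm <- function(v) { v <- v - mean(v); v / sqrt(sum(v^2)) }
  A <- nrm(x + y)
  B <- nrm(-x + y)
  C <- nrm(-y - 0.9 * (x^2 - mean(x^2)))
  D0 <- nrm(1 - 2 * x^2 - 2 * (y - 0.6)^2)
  D <- nrm(D0 - 0.45 * (sum(D0 * C) * C + sum(D0 * A) * A + sum(D0 * B) * B))
  maps <- cbind(A = A, B = B, C = C, D = D)
  rownames(maps) <- montage@channels
  new("TemplateSet", maps = maps, labels = c("A", "B", "C", "D"),
      gev = NA_real_, nRestarts = 0L, seed = as.integer(seed))
}

#' Per-group generator parameters
#'
#' @param occurrence target per-state occurrence rates (Hz); used as
#'   (normalized) run-type weights.
#' @param duration mean state dwell times (ms).
#' @param durationShape gamma shape of the dwell-time distribution
#'   (coefficient of variation = 1/sqrt(shape); default 8, a moderately
#'   narrow dwell spread that keeps sub-quarter-period dwells rare).
#' @param gfpScale per-state GFP at envelope maxima (microvolts).
#' @param topoJitter per-state topographic variability: each run's map is
#'   the template plus `topoJitter` times a white average-referenced map,
#'   renormalized (larger values lower the MsMC feature).
#' @return A named list of validated per-state parameters.
#' @export
groupParams <- function(occurrence, duration, durationShape = 8,
                        gfpScale, topoJitter = rep(0, 4)) {
  stopifnot(length(occurrence) == 4L, length(duration) == 4L,
            length(gfpScale) == 4L, length(topoJitter) == 4L)
  if (any(duration <= 0)) stop("all durations must be > 0")
  if (any(occurrence < 0) || sum(occurrence) <= 0)
    stop("occurrence weights must be nonnegative with positive sum")
  list(weights = occurrence / sum(occurrence),
       occurrence = occurrence, duration = duration,
       durationShape = durationShape, gfpScale = gfpScale,
       topoJitter = topoJitter)
}

#' Synthetic cohort configuration
#'
#' Defines the study conditions of the synthetic EEG cohort: two groups
#' ("HC", healthy-control-like, and "SZ", schizophrenia-like) whose
#' per-state occurrence, dwell time, GFP amplitude and topographic
#' variability defaults are calibrated to the reference group statistics.
#' The per-state GFP amplitudes are set so that the OBSERVED mean-GFP
#' feature (which mixes amplitude with dwell-length and boundary
#' attribution effects) lands on the reference values under the default
#' preprocessing; the raw amplitude numbers therefore differ from the
#' feature targets. Calibration anchors:
#' (HC occurrence 3.65/4.26/4.13/4.01 Hz, dwell 67.2/58.5/55.9/65.1 ms;
#' SZ occurrence 4.05/4.41/2.34/4.49 Hz, dwell 56.2/59.5/57.3/79.8 ms;
#' SZ GFP higher in all states; SZ topographic variability higher for
#' states A-C so that MsMC is lower, equal for D).
#'
#' @param nPerGroup subjects per group (default 14).
#' @param fs sampling rate in Hz (default 250).
#' @param duration recording length in seconds (default 900, i.e. 15 min).
#' @param montage a [Montage-class]; default 19-channel 10/20.
#' @param templates ground-truth [TemplateSet-class]; default
#'   `makeTemplates(montage)`.
#' @param hc,sz per-group parameter lists from [groupParams()].
#' @param envFreq amplitude-envelope frequency in Hz (default 10,
#'   the dominant resting eyes-closed alpha rate).
#' @param noiseSd spatially white sensor-noise SD (microvolts; default 0.8,
#'   about 10 percent of the GFP amplitude scale).
#' @param seed master seed; all per-subject seeds derive from it.
#' @return A validated configuration list of class `GeneratorConfig`.
#' @examples
#' cfg <- generatorConfig(nPerGroup = 1, duration = 10, seed = 7)
#' @export
generatorConfig <- function(nPerGroup = 14L, fs = 250, duration = 900,
                            montage = standardMontage1020(),
                            templates = makeTemplates(montage),
                            hc = groupParams(
                              occurrence = c(3.65, 4.26, 4.13, 4.01),
                              duration = c(67.18, 58.46, 55.91, 65.07),
                              gfpScale = c(7.606, 8.521, 8.748, 9.832),
                              topoJitter = c(0.080, 0.075, 0.070, 0.065)),
                            sz = groupParams(
                              occurrence = c(4.05, 4.41, 2.34, 4.49),
                              duration = c(56.22, 59.49, 57.29, 79.79),
                              gfpScale = c(8.669, 8.902, 8.948, 9.590),
                              topoJitter = c(0.084, 0.079, 0.080, 0.065)),
                            envFreq = 10, noiseSd = 0.8, seed = 1L) {
  if (nPerGroup < 1L) stop("nPerGroup must be >= 1")
  if (duration <= 0) stop("duration must be > 0")
  if (fs <= 2 * envFreq)
    stop("fs must exceed twice the envelope frequency")
  if (nrow(templates@maps) != length(montage@channels))
    stop("templates must be defined on the montage")
  cfg <- list(nPerGroup = as.integer(nPerGroup), fs = fs,
              duration = duration, montage = montage,
              templates = templates, groups = list(HC = hc, SZ = sz),
              envFreq = envFreq, noiseSd = noiseSd,
              seed = as.integer(seed))
  class(cfg) <- "GeneratorConfig"
  cfg
}

#' Sample a semi-Markov microstate state sequence
#'
#' States are drawn with self-transitions forbidden (the weight of the
#' current state is zeroed and the rest renormalized); dwell times are
#' gamma distributed with the state's mean duration and the configured
#' shape, discretized to samples (minimum 2 samples). Because the
#' no-self-transition renormalization would otherwise inflate the run
#' frequency of low-weight states, the raw drawing weights are first
#' calibrated (fixed-point iteration on the chain's stationary
#' distribution) so that the realized run-type frequencies match the
#' configured occurrence weights.
#'
#' @param config a `GeneratorConfig`.
#' @param group `"HC"` or `"SZ"`.
#' @param seed integer seed.
#' @return Character vector of per-sample labels (`A`-`D`) of length
#'   `fs * duration`, with an attribute `runs` holding the run-length
#'   encoding actually generated.
#' @export
sampleStateSequence <- function(config, group = c("HC", "SZ"), seed = 1L) {
  group <- match.arg(group)
  par <- config$groups[[group]]
  if (sum(par$weights > 0) < 2L)
    stop("at least two states need positive weight (self-transitions are forbidden)")
  w <- calibrateRunWeights(par$weights)
  set.seed(as.integer(seed))
  n <- round(config$fs * config$duration)
  maxRuns <- n %/% 2L + 1L            # dwell times are >= 2 samples
  states <- integer(maxRuns); lens <- integer(maxRuns)
  cur <- 0L; tot <- 0L; k <- 0L
  while (tot < n) {
    p <- w
    if (cur > 0L) p[cur] <- 0
    s <- sample.int(4L, 1L, prob = p)
    L <- rgamma(1L, shape = par$durationShape,
                scale = par$duration[s] / par$durationShape)
    L <- max(2L, as.integer(round(L / 1000 * config$fs)))
    L <- min(L, n - tot)
    k <- k + 1L
    states[k] <- s; lens[k] <- L
    tot <- tot + L; cur <- s
  }
  states <- states[seq_len(k)]; lens <- lens[seq_len(k)]
  lab <- rep(c("A", "B", "C", "D")[states], lens)
  attr(lab, "runs") <- list(states = c("A", "B", "C", "D")[states],
                            lengths = lens)
  return(lab)
}

# drawing weights whose no-self-transition chain has stationary run-type
# frequencies equal to the targets (fixed-point iteration)
calibrateRunWeights <- function(p) {
  p <- p / sum(p)
  act <- p > 0
  w <- p
  for (it in 1:200) {
    # stationary distribution of P(s | c) = w_s / (1 - w_c), s != c
    M <- outer(1 / (1 - w[act]), w[act])
    diag(M) <- 0
    M <- M / rowSums(M)
    e <- Re(eigen(t(M))$vectors[, 1])
    pi_ <- e / sum(e)
    if (max(abs(pi_ - p[act])) < 1e-10) break
    w[act] <- w[act] * (p[act] / pi_)^0.8
    w[act] <- w[act] / sum(w[act])
  }
  w
}

#' Synthesize a recording from a state sequence
#'
#' Forward model: within each dwell run the signal is the run's topography
#' times a sinusoidal carrier at `envFreq` (an alpha-like oscillation
#' whose polarity alternates, as in real EEG; microstate analysis is
#' polarity invariant), phase-locked to rise from zero at the run onset.
#' State transitions therefore sit at GFP minima and every dwell longer
#' than a quarter carrier period carries a GFP maximum, mirroring the
#' empirical observation that microstates switch at troughs of the global
#' field power. The GFP envelope is the rectified carrier, and the
#' amplitude is scaled so that the GFP at envelope maxima equals the
#' state's configured `gfpScale`. The run topography is the ground-truth
#' template, perturbed by the group's `topoJitter` (fixed within a run).
#' Spatially white Gaussian sensor noise is re-referenced to zero channel
#' mean and added; with `noiseSd = 0` and zero jitter, the topography at
#' every GFP peak equals the active template up to scaling.
#'
#' @param sequence per-sample labels from [sampleStateSequence()].
#' @param templates ground-truth [TemplateSet-class] (alphabet must match
#'   the sequence labels).
#' @param config a `GeneratorConfig`.
#' @param group group label (selects amplitude/jitter parameters).
#' @param seed integer seed (jitter + noise).
#' @param subjectId subject identifier attached to the recording.
#' @return A list with elements `recording` ([EEGRecording-class]) and
#'   `truth` (list: per-sample `labels`, `runs`, `templates`, `group`,
#'   `seed`).
#' @export
synthesizeRecording <- function(sequence, templates, config,
                                group = c("HC", "SZ"), seed = 1L,
                                subjectId = "S01") {
  group <- match.arg(group)
  if (!all(unique(sequence) %in% templates@labels))
    stop("sequence alphabet must match template labels")
  nch <- nrow(templates@maps)
  if (nch != length(config$montage@channels))
    stop("template channel count must match the montage")
  par <- config$groups[[group]]
  runs <- attr(sequence, "runs")
  if (is.null(runs)) {
    r <- rle(as.vector(sequence))
    runs <- list(states = r$values, lengths = r$lengths)
  }
  set.seed(as.integer(seed))
  sidx <- match(runs$states, templates@labels)
  n <- length(sequence)
  # per-run carrier: sine rising from zero at onset, so state transitions
  # sit at GFP minima and each dwell carries a GFP maximum ~quarter period in
  env <- unlist(lapply(runs$lengths, function(L)
    sin(2 * pi * config$envFreq * (0:(L - 1)) / config$fs)),
    use.names = FALSE)
  # per-run topography (template + fixed-within-run jitter, renormalized)
  runMaps <- templates@maps[, sidx, drop = FALSE]
  jit <- par$topoJitter[sidx]
  if (any(jit > 0)) {
    Z <- matrix(rnorm(nch * length(sidx)), nch)
    Z <- sweep(Z, 2, colMeans(Z))
    runMaps <- runMaps + sweep(Z, 2, jit, `*`)
    runMaps <- sweep(runMaps, 2, colMeans(runMaps))
    runMaps <- sweep(runMaps, 2, sqrt(colSums(runMaps^2)), `/`)
  }
  runOfSample <- rep(seq_along(runs$lengths), runs$lengths)
  amp <- par$gfpScale[sidx][runOfSample] * sqrt(nch) * env
  X <- runMaps[, runOfSample, drop = FALSE] * rep(amp, each = nch)
  if (config$noiseSd > 0) {
    N <- matrix(rnorm(nch * n, 0, config$noiseSd), nch)
    N <- sweep(N, 2, colMeans(N))   # keep the average-reference invariant
    X <- X + N
  }
  dimnames(X) <- list(config$montage@channels, NULL)
  rec <- new("EEGRecording", data = X, fs = config$fs,
             montage = config$montage, subjectId = subjectId,
             group = group)
  truth <- list(labels = as.vector(sequence), runs = runs,
                templates = templates, group = group,
                seed = as.integer(seed))
  list(recording = rec, truth = truth)
}

#' Generate a two-group synthetic EEG cohort
#'
#' Generates `2 * nPerGroup` recordings with per-subject seeds derived
#' deterministically from the master seed, so the whole cohort is
#' reproducible from the configuration alone.
#'
#' @param config a `GeneratorConfig` from [generatorConfig()].
#' @return A list with `recordings` (list of [EEGRecording-class]) and
#'   `truths` (matched list of ground-truth lists).
#' @examples
#' cfg <- generatorConfig(nPerGroup = 1, duration = 10, seed = 7)
#' coh <- generateCohort(cfg)
#' length(coh$recordings)
#' @export
generateCohort <- function(config) {
  set.seed(config$seed)
  nsub <- 2L * config$nPerGroup
  subSeeds <- sample.int(.Machine$integer.max - 1L, 2L * nsub)
  recs <- vector("list", nsub)
  truths <- vector("list", nsub)
  k <- 0L
  for (group in c("HC", "SZ")) for (i in seq_len(config$nPerGroup)) {
    k <- k + 1L
    sid <- sprintf("%s%02d", group, i)
    seq_ <- sampleStateSequence(config, group, seed = subSeeds[2L * k - 1L])
    out <- synthesizeRecording(seq_, config$templates, config, group,
                               seed = subSeeds[2L * k], subjectId = sid)
    recs[[k]] <- out$recording
    truths[[k]] <- out$truth
  }
  names(recs) <- names(truths) <- vapply(recs, subjectId, character(1))
  list(recordings = recs, truths = truths, config = config)
}

#' Simulate a feature table with known informative features
#'
#' A benchmark table for feature-ranking validity: `nInformative` features
#' differ between the two balanced classes by `effectSize` (in SD units);
#' the remaining `nNoise` features are standard normal in both classes.
#'
#' @param nRows total rows (split evenly between classes `HC` and `SZ`).
#' @param nInformative,nNoise feature counts.
#' @param effectSize standardized group mean difference of the informative
#'   features (default 0.8).
#' @param seed integer seed.
#' @return A data.frame with `subject_id`, `group` and the features;
#'   informative columns are named `inf1..`, noise columns `noise1..`.
#' @export
simulateRankingTable <- function(nRows = 500L, nInformative = 6L,
                                 nNoise = 14L, effectSize = 0.8,
                                 seed = 1L) {
  set.seed(as.integer(seed))
  n1 <- nRows %/% 2L; n2 <- nRows - n1
  grp <- rep(c("HC", "SZ"), c(n1, n2))
  shift <- ifelse(grp == "SZ", effectSize, 0)
  X <- matrix(rnorm(nRows * (nInformative + nNoise)), nRows)
  X[, seq_len(nInformative)] <- X[, seq_len(nInformative)] + shift
  colnames(X) <- c(sprintf("inf%d", seq_len(nInformative)),
                   sprintf("noise%d", seq_len(nNoise)))
  data.frame(subject_id = sprintf("r%04d", seq_len(nRows)), group = grp,
             X, stringsAsFactors = FALSE)
}
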