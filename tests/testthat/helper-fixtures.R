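# Shared fixtures, built in code.

# tiny preprocessed cohort (cached per session): nPerGroup subjects,
# durationS seconds each, default generator conditions
.fixtureCache <- new.env(parent = emptyenv())

tinyCohortEpochs <- function(nPerGroup = 2, durationS = 30, seed = 401) {
  key <- paste("coh", nPerGroup, durationS, seed, sep = "_")
  if (!is.null(.fixtureCache[[key]])) return(.fixtureCache[[key]])
  cfg <- generatorConfig(nPerGroup = nPerGroup, duration = durationS,
                         seed = seed)
  coh <- generateCohort(cfg)
  es <- lapply(coh$recordings, function(r)
    rejectOutlierEpochs(epochSignal(averageReference(bandpassFilter(r)), 5)))
  out <- list(config = cfg, cohort = coh, epochs = es)
  .fixtureCache[[key]] <- out
  out
}

pooledPeaks <- function(epochSets) {
  pks <- lapply(epochSets, extractPeakMaps)
  maps <- do.call(cbind, lapply(pks, peakMaps))
  g <- unlist(lapply(pks, peakGFP), use.names = FALSE)
  new("PeakSet", indices = seq_along(g), maps = maps, gfp = g)
}

# brute-force GEV maximizer over all assignments of <= 8 peaks
# (eigenvector template per cluster, both clusters non-empty)
bruteForceGEV <- function(maps, gfp, K = 2) {
  P <- ncol(maps)
  U <- apply(maps, 2, function(v) { v <- v - mean(v); v / sqrt(sum(v^2)) })
  best <- -Inf
  for (m in 0:(2^P - 1)) {
    a <- as.integer(intToBits(m))[1:P] + 1L
    if (length(unique(a)) < K) next
    r <- numeric(P)
    for (k in 1:K) {
      sel <- a == k
      M <- U[, sel, drop = FALSE]
      t_ <- eigen(tcrossprod(M * rep(gfp[sel], each = nrow(M))),
                  symmetric = TRUE)$vectors[, 1]
      r[sel] <- abs(colSums(M * t_))
    }
    gv <- sum((gfp * r)^2) / sum(gfp^2)
    if (gv > best) best <- gv
  }
  best
}

# microstate-like tiny peak set: maps drawn from two templates with
# polarity flips, 15% spatial noise and GFP weights in 2..6 uV
tinyPeakSet <- function(seed, P = NULL, noise = 0.15) {
  tpl <- templateMaps(makeTemplates(standardMontage1020()))
  set.seed(seed)
  if (is.null(P)) P <- sample(4:8, 1)
  which_t <- sample(1:2, P, replace = TRUE)
  signs <- sample(c(-1, 1), P, replace = TRUE)
  maps <- tpl[, which_t] * rep(signs, each = 19) +
    matrix(rnorm(19 * P, 0, noise), 19)
  maps <- sweep(maps, 2, colMeans(maps))
  new("PeakSet", indices = seq_len(P), maps = maps,
      gfp = runif(P, 2, 6))
}

# separable two-Gaussian feature table for classification tests
blobTable <- function(n = 60, d = 4, sep = 4, seed = 11) {
  set.seed(seed)
  grp <- rep(c("HC", "SZ"), each = n / 2)
  X <- matrix(rnorm(n * d), n)
  X[grp == "SZ", 1:2] <- X[grp == "SZ", 1:2] + sep
  colnames(X) <- sprintf("f%d", seq_len(d))
  data.frame(subject_id = sprintf("s%02d", rep(seq_len(n / 6), length.out = n)),
             group = grp, X, stringsAsFactors = FALSE)
}

# build a segmentation object directly from labeled runs (ms)
segFromRuns <- function(states, lengthsMs, fs = 250) {
  lens <- round(lengthsMs / 1000 * fs)
  lab <- rep(states, lens)
  new("MicrostateSegmentation", labels = lab,
      peakIndices = as.integer(cumsum(lens) - lens + 1L),
      peakLabels = states,
      peakCorrelations = rep(1, length(states)),
      gev = 1, fs = fs)
}

# 1-D quadratic search space stub for optimizer tests
quadraticSpace <- function(lo = -2, hi = 2) {
  list(quad = list(
    name = "quad", logCols = character(0),
    sample = function(n) data.frame(x = runif(n, lo, hi)),
    fit = function(par, X, y, seed) stop("stub"),
    score = function(model, X, ...) stop("stub")))
}

# recovery-study fixture shared by the template/parameter-recovery and
# conservation checks: 4 subjects per group, 60 s each, default noise
# (~10% of the GFP amplitude scale), one fixed seed
recoveryFixture <- function(seed = 42) {
  key <- paste0("recovery_", seed)
  if (!is.null(.fixtureCache[[key]])) return(.fixtureCache[[key]])
  fx <- tinyCohortEpochs(nPerGroup = 4, durationS = 60, seed = seed)
  km <- modifiedKMeans(pooledPeaks(fx$epochs), K = 4, nRestarts = 20,
                       seed = seed)
  tpl <- assignCanonicalLabels(km$templates,
                               makeTemplates(standardMontage1020()))
  tab <- extractFeatureTable(fx$epochs, tpl)
  out <- list(config = fx$config, epochs = fx$epochs, templates = tpl,
              features = tab)
  .fixtureCache[[key]] <- out
  out
}
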