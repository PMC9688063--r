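test_that("GFP matches its defining spatial RMS on hand cases", {
  expect_identical(computeGFP(c(3, 3, 3, 3)), 0)
  expect_identical(computeGFP(c(1, -1)), 1)
  expect_equal(computeGFP(c(2, 0, 1, 1)), sqrt(0.5), tolerance = 1e-15)
  M <- cbind(c(2, 0, 1, 1), c(5, 5, 5, 5))
  expect_equal(computeGFP(M), c(sqrt(0.5), 0), tolerance = 1e-15)
  expect_error(computeGFP(3), "2 channels")
})

test_that("GFP peak detection follows the strict-left / plateau rule", {
  expect_identical(detectGFPPeaks(c(0, 1, 0, 2, 0)), c(2L, 4L))
  expect_identical(detectGFPPeaks(1:10), integer(0))
  expect_identical(detectGFPPeaks(rep(1, 10)), integer(0))
  expect_identical(detectGFPPeaks(c(0, 1, 1, 0)), 2L)  # plateau: first sample
  expect_error(detectGFPPeaks(c(1, 2)), "3 samples")
})

test_that("spatial correlation is polarity-invariant Pearson", {
  v <- c(1, 2, -3, 0.5)
  expect_equal(spatialCorrelation(v, v), 1)
  expect_equal(spatialCorrelation(v, -v), 1)
  expect_equal(spatialCorrelation(v, -v, polarityInvariant = FALSE), -1)
  expect_lt(abs(spatialCorrelation(c(1, -1, 0, 0), c(0, 0, 1, -1))), 1e-12)
  expect_error(spatialCorrelation(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("modified K-means recovers orthogonal planted templates", {
  set.seed(10)
  T1 <- c(1, -1, 0, 0, 0, 0) / sqrt(2)
  T2 <- c(0, 0, 1, -1, 0, 0) / sqrt(2)
  maps <- cbind(T1, -T1, T1, T2, -T2, T2) * rep(runif(6, 1, 3), each = 6)
  pk <- new("PeakSet", indices = 1:6, maps = maps, gfp = runif(6, 1, 2))
  km <- modifiedKMeans(pk, K = 2, nRestarts = 5, seed = 1)
  expect_equal(gev(km$templates), 1, tolerance = 1e-12)
  got <- templateMaps(km$templates)
  match1 <- max(abs(cor(got[, 1], T1)), abs(cor(got[, 1], T2)))
  match2 <- max(abs(cor(got[, 2], T1)), abs(cor(got[, 2], T2)))
  expect_equal(c(match1, match2), c(1, 1), tolerance = 1e-9)
  expect_error(modifiedKMeans(pk, K = 7), "fewer peaks")
})

test_that("K = number of peaks gives GEV 1", {
  pk <- tinyPeakSet(3, P = 5)
  km <- modifiedKMeans(pk, K = 5, nRestarts = 3, seed = 2)
  expect_equal(gev(km$templates), 1, tolerance = 1e-9)
})

test_that("clustering is invariant to sign flips of input maps", {
  pk <- tinyPeakSet(7, P = 8)
  km1 <- modifiedKMeans(pk, K = 2, seed = 4)
  flip <- rep(c(1, -1), 4)
  pk2 <- new("PeakSet", indices = pk@indices,
             maps = pk@maps * rep(flip, each = nrow(pk@maps)),
             gfp = pk@gfp)
  km2 <- modifiedKMeans(pk2, K = 2, seed = 4)
  expect_equal(gev(km1$templates), gev(km2$templates), tolerance = 1e-12)
  C <- abs(cor(templateMaps(km1$templates), templateMaps(km2$templates)))
  expect_equal(unname(apply(C, 1, max)), c(1, 1), tolerance = 1e-9)
})

test_that("clustering is deterministic given the seed", {
  pk <- tinyPeakSet(12, P = 8)
  km1 <- modifiedKMeans(pk, K = 3, seed = 5)
  km2 <- modifiedKMeans(pk, K = 3, seed = 5)
  expect_identical(templateMaps(km1$templates), templateMaps(km2$templates))
  expect_identical(km1$assignments, km2$assignments)
})

test_that("GEV matches its defining formula", {
  # two peaks, GFP (1, 2), correlations (1, 0.5) -> 0.4
  t1 <- c(1, -1, 0, 0) / sqrt(2)
  m2 <- t1 * 0.5 + sqrt(1 - 0.25) * c(0, 0, 1, -1) / sqrt(2)
  pk <- new("PeakSet", indices = 1:2, maps = cbind(t1, m2), gfp = c(1, 2))
  tpl <- new("TemplateSet", maps = cbind(M1 = t1), labels = "M1",
             gev = NA_real_, nRestarts = 0L, seed = 0L)
  expect_equal(computeGEV(pk, c(1L, 1L), tpl), 0.4, tolerance = 1e-12)
  # collinear and orthogonal extremes
  pkc <- new("PeakSet", indices = 1:2, maps = cbind(t1, -2 * t1),
             gfp = c(1, 2))
  expect_equal(computeGEV(pkc, c(1L, 1L), tpl), 1, tolerance = 1e-12)
  orth <- c(0, 0, 1, -1) / sqrt(2)
  pko <- new("PeakSet", indices = 1:2, maps = cbind(orth, 3 * orth),
             gfp = c(1, 2))
  expect_lt(computeGEV(pko, c(1L, 1L), tpl), 1e-20)
})

test_that("GEV is non-decreasing in K on a fixed peak set", {
  pk <- tinyPeakSet(20, P = 40)
  gevs <- vapply(2:6, function(K)
    gev(modifiedKMeans(pk, K = K, nRestarts = 10, seed = 6)$templates),
    numeric(1))
  expect_true(all(diff(gevs) >= -1e-9))
})

test_that("canonical labeling recovers permutations and polarity", {
  canon <- makeTemplates(standardMontage1020())
  relabel <- function(ts) stateLabels(assignCanonicalLabels(ts, canon))
  expect_identical(relabel(canon), c("A", "B", "C", "D"))
  swapped <- initialize(canon, maps = canon@maps[, c(2, 1, 3, 4)],
                        labels = c("M1", "M2", "M3", "M4"))
  out <- assignCanonicalLabels(swapped, canon)
  expect_equal(unname(abs(diag(cor(templateMaps(out), templateMaps(canon))))),
               rep(1, 4), tolerance = 1e-12)
  neg <- initialize(canon, maps = -canon@maps,
                    labels = c("M1", "M2", "M3", "M4"))
  outn <- assignCanonicalLabels(neg, canon)
  expect_equal(unname(abs(diag(cor(templateMaps(outn), templateMaps(canon))))),
               rep(1, 4), tolerance = 1e-12)
  m10 <- apply(canon@maps[1:10, ], 2,
               function(v) { v <- v - mean(v); v / sqrt(sum(v^2)) })
  small <- new("TemplateSet", maps = m10, labels = canon@labels,
               gev = NA_real_, nRestarts = 0L, seed = 0L)
  expect_error(assignCanonicalLabels(small, canon), "montage mismatch")
})

test_that("backfitting applies the nearest-peak midpoint rule", {
  # construct a 40-sample epoch with exactly two GFP peaks at 11 and 21
  t1 <- c(1, -1, 0, 0, 0) / sqrt(2)
  t2 <- c(0, 0, 1, -1, 0) / sqrt(2)
  tpl <- new("TemplateSet", maps = cbind(A = t1, B = t2),
             labels = c("A", "B"), gev = NA_real_, nRestarts = 0L,
             seed = 0L)
  X <- matrix(0, 5, 40)
  bump <- function(center, map, X) {
    prof <- pmax(0, 1 - abs(seq_len(40) - center) / 6)
    X + outer(map, prof)
  }
  X <- bump(11, t1, X); X <- bump(21, t2, X)
  X <- X + outer(t1, rep(0.01, 40))   # tiny floor so no zero frames
  seg <- backfitLabels(X, tpl, fs = 250)
  expect_identical(peakIndices(seg), c(11L, 21L))
  expect_identical(seg@peakLabels, c("A", "B"))
  expect_identical(stateLabels(seg)[1:16], rep("A", 16))
  expect_identical(stateLabels(seg)[17:40], rep("B", 24))
  # single peak: whole epoch inherits its label
  X1 <- bump(11, t1, matrix(0, 5, 40)) + outer(t1, rep(0.01, 40))
  seg1 <- backfitLabels(X1, tpl, fs = 250)
  expect_identical(unique(stateLabels(seg1)), "A")
  expect_error(backfitLabels(matrix(rep(c(1, 2, 1, 0, 0), 9), 5), tpl, 250),
               "no GFP peaks")
})

test_that("noiseless epochs backfit to the ground-truth labels", {
  # dwell times long relative to the 50 ms peak spacing, so that the
  # midpoint-rule boundary blur (bounded by half the peak spacing per
  # transition) stays below 5% of the samples
  zeroJit <- groupParams(occurrence = c(3.65, 4.26, 4.13, 4.01),
                         duration = c(260, 240, 220, 250),
                         gfpScale = rep(8, 4), topoJitter = rep(0, 4))
  cfg <- generatorConfig(nPerGroup = 1, duration = 10, noiseSd = 0,
                         hc = zeroJit, seed = 31)
  lab <- sampleStateSequence(cfg, "HC", seed = 31)
  out <- synthesizeRecording(lab, cfg$templates, cfg, "HC", seed = 31)
  X <- recordingData(out$recording)
  seg <- backfitLabels(X, cfg$templates, fs = 250)
  agree <- mean(stateLabels(seg) == out$truth$labels)
  expect_gte(agree, 0.95)
})
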