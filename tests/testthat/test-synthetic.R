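test_that("ground-truth templates are normalized, distinct and deterministic", {
  mont <- standardMontage1020()
  tpl <- makeTemplates(mont)
  maps <- templateMaps(tpl)
  expect_identical(stateLabels(tpl), c("A", "B", "C", "D"))
  expect_equal(unname(colMeans(maps)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(sqrt(colSums(maps^2))), rep(1, 4), tolerance = 1e-12)
  cors <- abs(cor(maps))
  expect_true(all(cors[upper.tri(cors)] <= 0.7))
  expect_identical(maps, templateMaps(makeTemplates(mont)))
  expect_error(makeTemplates(montage(c("a", "b", "c"),
                                     cbind(c(0, .1, .2), c(0, 0, 0)))),
               "at least 4")
})

test_that("state sequences honor dwell and occurrence targets", {
  cfg <- generatorConfig(nPerGroup = 1, duration = 900, seed = 5)
  lab <- sampleStateSequence(cfg, "HC", seed = 5)
  expect_length(lab, 900 * 250)
  expect_setequal(unique(lab), c("A", "B", "C", "D"))
  runs <- attr(lab, "runs")
  expect_false(any(runs$states[-1] == runs$states[-length(runs$states)]))
  # empirical per-state mean dwell within 15% of the configured mean
  for (s in c("A", "B", "C", "D")) {
    i <- match(s, c("A", "B", "C", "D"))
    est <- mean(runs$lengths[runs$states == s]) * 4   # ms at 250 Hz
    expect_lt(abs(est / cfg$groups$HC$duration[i] - 1), 0.15)
  }
  # occurrence-weight calibration: realized run frequencies near targets
  p <- as.vector(table(factor(runs$states, c("A", "B", "C", "D"))))
  p <- p / sum(p)
  expect_lt(max(abs(p - cfg$groups$HC$weights)), 0.02)
  expect_identical(as.vector(lab),
                   as.vector(sampleStateSequence(cfg, "HC", seed = 5)))
  expect_false(identical(as.vector(lab),
                         as.vector(sampleStateSequence(cfg, "HC", seed = 6))))
})

test_that("degenerate occurrence weights are rejected", {
  expect_error(groupParams(occurrence = c(0, 0, 0, 0),
                           duration = rep(60, 4), gfpScale = rep(5, 4)),
               "positive sum")
  cfg <- generatorConfig(nPerGroup = 1, duration = 5, seed = 1,
                         hc = groupParams(occurrence = c(1, 0, 0, 0),
                                          duration = rep(60, 4),
                                          gfpScale = rep(5, 4)))
  expect_error(sampleStateSequence(cfg, "HC", 1), "two states")
})

test_that("noiseless forward model reproduces templates at GFP peaks", {
  zeroJit <- function(occ, dur, g)
    groupParams(occurrence = occ, duration = dur, gfpScale = g,
                topoJitter = rep(0, 4))
  cfg <- generatorConfig(nPerGroup = 1, duration = 10, noiseSd = 0,
                         hc = zeroJit(c(3.65, 4.26, 4.13, 4.01),
                                      c(67, 58, 56, 65), rep(8, 4)),
                         seed = 9)
  lab <- sampleStateSequence(cfg, "HC", seed = 9)
  out <- synthesizeRecording(lab, cfg$templates, cfg, "HC", seed = 9,
                             subjectId = "T1")
  X <- recordingData(out$recording)
  expect_identical(ncol(X), 2500L)
  g <- computeGFP(X)
  pk <- detectGFPPeaks(g)
  tpl <- templateMaps(cfg$templates)
  r <- vapply(pk, function(i)
    spatialCorrelation(X[, i], tpl[, out$truth$labels[i]]), numeric(1))
  expect_equal(r, rep(1, length(pk)), tolerance = 1e-9)
  # GFP at any sample equals the hand-evaluated spatial RMS of that frame
  i <- pk[1]
  expect_equal(g[i], sqrt(sum((X[, i] - mean(X[, i]))^2) / 19),
               tolerance = 1e-12)
  # GFP equals the configured scale times the sampled carrier everywhere:
  # evaluate the forward model's envelope directly and compare
  runs <- out$truth$runs
  off <- sequence(runs$lengths) - 1L
  env <- abs(sin(2 * pi * 10 * off / 250))
  expect_equal(g, 8 * env, tolerance = 1e-9)
  # peaks never exceed the configured amplitude scale
  expect_true(all(g[pk] <= 8 + 1e-9))
})

test_that("cohorts have the configured size and are seed-reproducible", {
  cfg <- generatorConfig(nPerGroup = 1, duration = 10, seed = 77)
  coh <- generateCohort(cfg)
  expect_length(coh$recordings, 2L)
  expect_identical(vapply(coh$recordings, groupLabel, character(1)),
                   c(HC01 = "HC", SZ01 = "SZ"))
  expect_identical(ncol(recordingData(coh$recordings[[1]])), 2500L)
  coh2 <- generateCohort(cfg)
  expect_identical(recordingData(coh$recordings[[2]]),
                   recordingData(coh2$recordings[[2]]))
  coh3 <- generateCohort(generatorConfig(nPerGroup = 1, duration = 10,
                                         seed = 78))
  expect_false(identical(recordingData(coh$recordings[[1]]),
                         recordingData(coh3$recordings[[1]])))
})

test_that("generated frames keep the average-reference invariant", {
  cfg <- generatorConfig(nPerGroup = 1, duration = 5, seed = 3)
  coh <- generateCohort(cfg)
  X <- recordingData(coh$recordings[[1]])
  expect_lt(max(abs(colMeans(X))), 1e-10)
})

test_that("ranking benchmark table has the stated design", {
  tab <- simulateRankingTable(nRows = 100, nInformative = 3, nNoise = 5,
                              effectSize = 1, seed = 2)
  expect_identical(dim(tab), c(100L, 10L))
  expect_identical(sum(tab$group == "SZ"), 50L)
  d <- mean(tab$inf1[tab$group == "SZ"]) - mean(tab$inf1[tab$group == "HC"])
  expect_gt(d, 0.5)
  expect_identical(tab, simulateRankingTable(100, 3, 5, 1, seed = 2))
})
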