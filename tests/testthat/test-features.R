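test_that("run statistics match hand-computed values", {
  # A(2000 ms) B(2000 ms) A(1000 ms) in a 5-s epoch
  seg <- segFromRuns(c("A", "B", "A"), c(2000, 2000, 1000))
  expect_equal(occurrence(seg, "A"), 0.4)
  expect_equal(occurrence(seg, "B"), 0.2)
  expect_equal(occurrence(seg, "C"), 0)
  expect_equal(duration(seg, "A"), 1500)
  expect_equal(duration(seg, "B"), 2000)
  expect_equal(duration(seg, "C"), 0)
  expect_equal(coverage(seg, "A"), 60)
  expect_equal(coverage(seg, "B"), 40)
  # occurrence x duration / 10 = coverage for partition labelings
  expect_equal(occurrence(seg, "A") * duration(seg, "A") / 10,
               coverage(seg, "A"), tolerance = 1e-12)
  single <- segFromRuns("A", 5000)
  expect_equal(occurrence(single, "A"), 0.2)
  expect_equal(duration(single, "A"), 5000)
})

test_that("mean GFP averages over dominance samples only", {
  seg <- segFromRuns(c("A", "B"), c(3000, 2000))
  g <- ifelse(stateLabels(seg) == "A", 2, 4)
  expect_equal(meanGFP(seg, g, "A"), 2)
  expect_equal(meanGFP(seg, g, "B"), 4)
  expect_equal(meanGFP(seg, rep(5, length(g)), "A"), 5)
  expect_equal(meanGFP(seg, g, "C"), 0)
  expect_error(meanGFP(seg, g[-1], "A"), "aligned")
})

test_that("MsMC is the mean absolute peak correlation per state", {
  seg <- new("MicrostateSegmentation",
             labels = rep(c("A", "B"), c(10, 10)),
             peakIndices = c(3L, 7L, 14L),
             peakLabels = c("A", "A", "B"),
             peakCorrelations = c(0.8, 0.6, 0.9),
             gev = 0.5, fs = 250)
  expect_equal(msmc(seg, "A"), 0.7)
  expect_equal(msmc(seg, "B"), 0.9)
  expect_equal(msmc(seg, "C"), 0)
})

test_that("the feature table is complete, named and conserved", {
  fx <- tinyCohortEpochs(nPerGroup = 2, durationS = 30, seed = 401)
  tab <- extractFeatureTable(fx$epochs, fx$config$templates)
  states <- c("A", "B", "C", "D")
  expect_identical(setdiff(names(tab), c("subject_id", "group", "epoch")),
                   microstateFeatureNames(states))
  expect_identical(nrow(tab), 4L * 6L)
  expect_false(anyNA(tab))
  covSum <- rowSums(tab[paste0("Coverage_", states)])
  expect_equal(covSum, rep(100, nrow(tab)), tolerance = 1e-6)
  for (s in states) {
    lhs <- tab[[paste0("Occurrence_", s)]] * tab[[paste0("Duration_", s)]] / 10
    expect_equal(lhs, tab[[paste0("Coverage_", s)]], tolerance = 1e-9)
  }
  expect_true(all(tab[paste0("Occurrence_", states)] >= 0))
  msmcCols <- as.matrix(tab[paste0("MsMC_", states)])
  expect_true(all(msmcCols >= 0 & msmcCols <= 1))
  expect_s3_class(attr(tab, "flags"), "data.frame")
  # determinism
  tab2 <- extractFeatureTable(fx$epochs, fx$config$templates)
  expect_identical(tab, tab2)
})

test_that("group means reproduce every configured effect direction", {
  fx <- tinyCohortEpochs(nPerGroup = 4, durationS = 60, seed = 402)
  tab <- extractFeatureTable(fx$epochs, fx$config$templates)
  mHC <- colMeans(tab[tab$group == "HC", microstateFeatureNames()])
  mSZ <- colMeans(tab[tab$group == "SZ", microstateFeatureNames()])
  d <- mSZ - mHC
  # configured directions: SZ lower Occurrence_C/Coverage_C/MsMC_{A,B,C},
  # higher Duration_D/Coverage_D and mean GFP in all states
  expect_lt(d[["Occurrence_C"]], 0)
  expect_lt(d[["Coverage_C"]], 0)
  expect_gt(d[["Duration_D"]], 0)
  expect_gt(d[["Coverage_D"]], 0)
  for (s in c("A", "B", "C", "D")) expect_gt(d[[paste0("MeanGFP_", s)]], 0)
  for (s in c("A", "B", "C")) expect_lt(d[[paste0("MsMC_", s)]], 0)
})

test_that("subject aggregation averages epochs within subject", {
  fx <- tinyCohortEpochs(nPerGroup = 2, durationS = 30, seed = 401)
  tab <- extractFeatureTable(fx$epochs, fx$config$templates)
  agg <- aggregateBySubject(tab)
  expect_identical(nrow(agg), 4L)
  s1 <- agg[agg$subject_id == "HC01", "Occurrence_A"]
  expect_equal(s1, mean(tab$Occurrence_A[tab$subject_id == "HC01"]))
})
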