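quadObjective <- function(center = 0.7) {
  function(learnerName, params, seed) (params$x - center)^2
}

test_that("expected improvement matches its closed form", {
  expect_equal(expectedImprovement(0.5, 0, 0.5), 0)
  expect_equal(expectedImprovement(0.4, 0, 0.5), 0.1)
  expect_equal(expectedImprovement(0.5, 1, 0.5), 1 / sqrt(2 * pi),
               tolerance = 1e-12)
  # monotone: larger sd at equal mean cannot lower EI
  eis <- expectedImprovement(rep(0.5, 3), c(0.1, 0.5, 1), 0.5)
  expect_true(all(diff(eis) > 0))
  expect_error(expectedImprovement(0, -1, 0), "sd")
})

test_that("the CV objective is stratified, bounded and deterministic", {
  tab <- blobTable(n = 60, d = 4, sep = 4, seed = 31)
  lrn <- learnerPool()$discriminant
  par <- data.frame(type = "linear", gamma = 0.1)
  o1 <- cvObjective(lrn, par, tab, sprintf("f%d", 1:4), k = 5, seed = 7)
  o2 <- cvObjective(lrn, par, tab, sprintf("f%d", 1:4), k = 5, seed = 7)
  expect_identical(o1, o2)
  expect_lte(o1, 0.05)
  # a constant scorer degenerates to the majority error (0.5 balanced)
  stub <- list(name = "const", logCols = character(0),
               sample = function(n) data.frame(z = runif(n)),
               fit = function(par, X, y, seed) list(),
               score = function(model, X, ...) rep(0.3, nrow(X)))
  expect_equal(cvObjective(stub, data.frame(z = 0.5), tab,
                           sprintf("f%d", 1:4), k = 5, seed = 7), 0.5)
  single <- tab[tab$group == "HC", ]
  expect_error(cvObjective(lrn, par, single, sprintf("f%d", 1:4)),
               "single class")
})

test_that("EI refinement never degrades the initial-design incumbent", {
  space <- quadraticSpace(-2, 2)
  gridMin <- min((seq(-2, 2, length.out = 20000) - 0.7)^2)
  for (seed in 1:5) {
    bo <- bayesOptimize(space = space, budget = 30, nInit = 4, seed = seed,
                        objective = quadObjective(0.7))
    # the incumbent can only improve on the random initial design
    expect_lte(bo$best$objective, min(bo$trace$objective[1:4]))
    expect_lt(bo$best$objective - gridMin, 0.05)
    # incumbent-so-far is non-increasing along the trace
    expect_true(all(diff(cummin(bo$trace$objective)) <= 0))
    expect_identical(nrow(bo$trace), 30L)
  }
})

test_that("budget 1 returns the single evaluated random point", {
  bo <- bayesOptimize(space = quadraticSpace(), budget = 1, seed = 3,
                      objective = quadObjective(0))
  expect_identical(nrow(bo$trace), 1L)
  expect_identical(bo$incumbent, 1L)
})

test_that("optimization is reproducible given the seed", {
  tab <- blobTable(n = 60, d = 3, sep = 3, seed = 32)
  sub <- learnerPool()[c("discriminant", "tree", "linear")]
  b1 <- bayesOptimize(tab, sprintf("f%d", 1:3), space = sub, budget = 8,
                      nInit = 2, seed = 12)
  b2 <- bayesOptimize(tab, sprintf("f%d", 1:3), space = sub, budget = 8,
                      nInit = 2, seed = 12)
  expect_identical(b1$trace$objective, b2$trace$objective)
  expect_identical(b1$best$learner, b2$best$learner)
})

test_that("confusion metrics and AUC satisfy their identities", {
  m <- confusionMetrics(9, 1, 8, 2)
  expect_identical(c(m$accuracy, m$sensitivity, m$specificity),
                   c(85, 90, 80))
  labs <- rep(c("SZ", "HC"), each = 5)
  perfect <- c(6:10, 1:5)
  expect_identical(rankAUC(perfect, labs, "SZ"), 1)
  expect_identical(rankAUC(-perfect, labs, "SZ"), 0)
  # invariance under strictly monotone transform
  set.seed(2)
  sc <- rnorm(20); lb <- sample(c("HC", "SZ"), 20, replace = TRUE,
                                prob = c(.5, .5))
  if (length(unique(lb)) == 2)
    expect_equal(rankAUC(sc, lb, "SZ"), rankAUC(exp(sc), lb, "SZ"))
  # cross-check the rank form against an independent ROC implementation
  skip_if_not_installed("pROC")
  roc <- pROC::roc(response = lb, predictor = sc, levels = c("HC", "SZ"),
                   direction = "<", quiet = TRUE)
  expect_equal(rankAUC(sc, lb, "SZ"), as.numeric(pROC::auc(roc)),
               tolerance = 1e-12)
})

test_that("hold-out evaluation classifies separable cohorts", {
  tab <- blobTable(n = 120, d = 4, sep = 4, seed = 33)
  sub <- learnerPool()[c("discriminant", "linear", "tree")]
  rep1 <- evaluateHoldout(tab, sprintf("f%d", 1:4), budget = 6, nInit = 2,
                          seed = 14, space = sub)
  expect_gte(rep1$accuracy, 95)
  expect_gte(rep1$auc, 0.95)
  expect_identical(sum(rep1$confusion), 24L)   # 20% of 120
  rep2 <- evaluateHoldout(tab, sprintf("f%d", 1:4), budget = 6, nInit = 2,
                          seed = 14, space = sub)
  expect_identical(rep1$accuracy, rep2$accuracy)
  expect_identical(rep1$bestLearner, rep2$bestLearner)
})

test_that("LOSO folds never leak the held-out subjects", {
  tab <- blobTable(n = 120, d = 3, sep = 4, seed = 34)
  # 10 HC subjects s01..s10? blobTable repeats ids; rebuild explicit ids
  tab$subject_id <- sprintf("%s%02d", tab$group,
                            rep(rep(1:5, each = 12), length.out = 120))
  sub <- learnerPool()[c("discriminant", "linear")]
  rep_ <- leaveOneSubjectOut(tab, sprintf("f%d", 1:3), budget = 4, seed = 15,
                             space = sub)
  folds <- attr(rep_, "folds")
  expect_length(folds, 5L)
  expect_identical(sum(rep_$confusion), 120L)  # every epoch tested once
  expect_gte(rep_$accuracy, 90)
  expect_error(leaveOneSubjectOut(tab[tab$subject_id %in%
                                        c("HC01", "SZ01"), ],
                                  sprintf("f%d", 1:3), space = sub),
               "2 subjects")
})

test_that("incremental curves use the top-k ranked features in order", {
  tab <- blobTable(n = 80, d = 4, sep = 3, seed = 35)
  rk <- chi2RankFeatures(tab, nBins = 10)
  sub <- learnerPool()[c("discriminant", "tree")]
  cur <- incrementalFeatureCurve(tab, rk, kMax = 2, budget = 4, nInit = 2,
                                 seed = 16, space = sub)
  expect_length(cur, 2L)
  expect_identical(cur[[1]]$features, rk$feature[1])
  expect_identical(cur[[2]]$features, rk$feature[1:2])
  expect_error(incrementalFeatureCurve(tab, rk, kMax = 10), "exceeds")
})
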