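#' Stratified k-fold cross-validated misclassification rate
#'
#' Deterministic given the seed: fold membership is drawn per class, the
#' learner is fit on k-1 folds and all held-out predictions are pooled
#' into one misclassification rate.
#'
#' @param learner a descriptor from [learnerPool()].
#' @param params one-row data.frame of hyperparameters.
#' @param table feature table (`group` column + feature columns).
#' @param features character vector of feature columns to use.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @param posClass positive-class label (default `"SZ"`).
#' @return Misclassification rate in `[0, 1]`.
#' @export
cvObjective <- function(learner, params, table, features, k = 5L,
                        seed = 1L, posClass = "SZ") {
  if (k < 2L) stop("k must be >= 2")
  y <- classFactor(table$group, posClass)
  if (nlevels(droplevels(y)) < 2L) stop("training data has a single class")
  X <- as.matrix(table[, features, drop = FALSE])
  set.seed(as.integer(seed))
  fold <- integer(nrow(X))
  for (l in levels(y)) {
    idx <- sample(which(y == l))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  wrong <- 0L
  for (f in seq_len(k)) {
    tr <- fold != f
    fit <- fitLearner(learner, params, X[tr, , drop = FALSE], y[tr],
                      seed = as.integer(seed) + f)
    pr <- predictLearner(fit, X[!tr, , drop = FALSE])
    wrong <- wrong + sum(pr$class != as.character(y[!tr]))
  }
  wrong / nrow(X)
}

# two-level factor with the positive class as the SECOND level
classFactor <- function(g, posClass) {
  neg <- setdiff(unique(as.character(g)), posClass)
  if (length(neg) != 1L) stop("expected exactly two classes")
  factor(as.character(g), levels = c(neg, posClass))
}

#' Expected improvement acquisition
#'
#' `EI = E[max(incumbent - Y, 0)]` for `Y ~ Normal(mean, sd^2)`
#' (minimization), in closed form; at `sd = 0` it degenerates to
#' `max(incumbent - mean, 0)`.
#'
#' @param mean,sd surrogate predictive mean and standard deviation
#'   (vectorized; `sd >= 0`).
#' @param incumbent best (lowest) objective value observed so far.
#' @return EI values (>= 0).
#' @export
expectedImprovement <- function(mean, sd, incumbent) {
  stopifnot(all(sd >= 0))
  out <- pmax(incumbent - mean, 0)
  pos <- sd > 0
  if (any(pos)) {
    z <- (incumbent - mean[pos]) / sd[pos]
    out[pos] <- (incumbent - mean[pos]) * stats::pnorm(z) +
      sd[pos] * stats::dnorm(z)
  }
  out
}

# numeric/factor encoding of a learner's sampled configurations for the
# random-forest surrogate (log-scale columns transformed)
encodeParams <- function(learner, df) {
  out <- df
  for (cl in learner$logCols) out[[cl]] <- log(out[[cl]])
  for (nm in names(out)) {
    if (!is.null(learner$catLevels[[nm]]))
      out[[nm]] <- factor(out[[nm]], levels = learner$catLevels[[nm]])
    else if (is.character(out[[nm]])) out[[nm]] <- factor(out[[nm]])
  }
  out
}

#' Bayesian optimization over the classifier pool
#'
#' Sequential model-based selection of a learner and its
#' hyperparameters. The first evaluations are random configurations,
#' `nInit` per learner in round-robin order (truncated if the budget is
#' smaller). Afterwards, each learner's evaluated points are modeled by a
#' regression random forest (one surrogate per learner); the predictive
#' mean and the spread of the per-tree predictions give the
#' expected-improvement score of `nCandidates` fresh random draws per
#' learner, and the candidate with the highest EI is evaluated next. The
#' incumbent is the configuration with the lowest objective value in the
#' trace. Deterministic given `seed`.
#'
#' @param table feature table (ignored when `objective` is supplied).
#' @param features feature columns to use.
#' @param space learner pool (default [learnerPool()]).
#' @param budget total number of objective evaluations (default 50).
#' @param nInit random initial designs per learner (default 4).
#' @param k CV folds for the default objective (default 5).
#' @param seed integer seed.
#' @param posClass positive-class label for the default objective.
#' @param nCandidates random EI candidates per learner per iteration
#'   (default 256).
#' @param objective optional function `(learnerName, params, seed)`
#'   returning the value to minimize, replacing the cross-validated
#'   misclassification objective (used for stubs and custom searches).
#' @return A list of class `OptimizationTrace`: `trace` (data.frame with
#'   learner, objective, evaluation seed and a list-column `params`),
#'   `incumbent` (row index), `best` (list: learner, params, objective).
#' @export
bayesOptimize <- function(table = NULL, features = NULL,
                          space = learnerPool(), budget = 50L,
                          nInit = 4L, k = 5L, seed = 1L, posClass = "SZ",
                          nCandidates = 256L, objective = NULL) {
  if (budget < 1L) stop("budget must be >= 1")
  if (is.null(objective)) {
    if (is.null(table)) stop("either a table or an objective is required")
    objective <- function(learnerName, params, seed)
      cvObjective(space[[learnerName]], params, table, features, k = k,
                  seed = seed, posClass = posClass)
  }
  set.seed(as.integer(seed))
  evalSeeds <- sample.int(.Machine$integer.max - 1L, budget)
  drawSeeds <- sample.int(.Machine$integer.max - 1L, budget + 1L)
  lnames <- names(space)
  trace <- data.frame(learner = character(0), objective = numeric(0),
                      seed = integer(0))
  paramsList <- list()
  evalOne <- function(learnerName, params, i) {
    val <- objective(learnerName, params, evalSeeds[i])
    trace[nrow(trace) + 1L, c("learner", "objective", "seed")] <<-
      list(learnerName, val, evalSeeds[i])
    paramsList[[length(paramsList) + 1L]] <<- params
    invisible(val)
  }
  # round-robin random initialization
  initPlan <- rep(lnames, nInit)[seq_len(min(budget, nInit * length(lnames)))]
  for (i in seq_along(initPlan)) {
    set.seed(drawSeeds[i])
    evalOne(initPlan[i], space[[initPlan[i]]]$sample(1L), i)
  }
  # EI-guided phase
  i <- length(initPlan)
  while (i < budget) {
    i <- i + 1L
    set.seed(drawSeeds[i])
    incumbent <- min(trace$objective)
    bestEI <- -Inf; bestLearner <- NULL; bestParams <- NULL
    for (ln in lnames) {
      rows <- which(trace$learner == ln)
      cand <- space[[ln]]$sample(nCandidates)
      if (length(rows) < 2L) {
        # not enough points for a surrogate: treat as pure exploration
        pick <- cand[1L, , drop = FALSE]
        ei <- Inf
      } else {
        Xs <- encodeParams(space[[ln]],
                           do.call(rbind, paramsList[rows]))
        dat <- cbind(Xs, .obj = trace$objective[rows])
        sg <- ranger::ranger(.obj ~ ., data = dat, num.trees = 100L,
                             min.node.size = 2L, seed = drawSeeds[i],
                             num.threads = 1)
        pr <- stats::predict(sg, encodeParams(space[[ln]], cand),
                             predict.all = TRUE, num.threads = 1)$predictions
        mu <- rowMeans(pr)
        sdv <- apply(pr, 1, stats::sd)
        eis <- expectedImprovement(mu, sdv, incumbent)
        jbest <- which.max(eis)
        pick <- cand[jbest, , drop = FALSE]
        ei <- eis[jbest]
      }
      if (ei > bestEI) {
        bestEI <- ei; bestLearner <- ln; bestParams <- pick
      }
    }
    evalOne(bestLearner, bestParams, i)
  }
  inc <- which.min(trace$objective)
  trace$params <- I(paramsList)
  structure(list(trace = trace, incumbent = inc,
                 best = list(learner = trace$learner[inc],
                             params = paramsList[[inc]],
                             objective = trace$objective[inc]),
                 seed = as.integer(seed)),
            class = "OptimizationTrace")
}

#' Classification metrics from a confusion matrix
#'
#' @param tp,fn,tn,fp confusion-matrix counts (positive = the condition
#'   of interest).
#' @return list with `accuracy`, `sensitivity`, `specificity` (percent)
#'   and the counts.
#' @examples
#' confusionMetrics(9, 1, 8, 2)  # 85 / 90 / 80
#' @export
confusionMetrics <- function(tp, fn, tn, fp) {
  list(accuracy = 100 * (tp + tn) / (tp + fn + tn + fp),
       sensitivity = 100 * tp / (tp + fn),
       specificity = 100 * tn / (tn + fp),
       tp = tp, fn = fn, tn = tn, fp = fp)
}

#' Rank-statistic AUC
#'
#' The Mann-Whitney form: the probability (with ties counted half) that
#' a random positive scores above a random negative. Invariant to
#' strictly monotone transforms of the score.
#'
#' @param scores numeric scores, larger = more positive.
#' @param labels class labels.
#' @param posClass positive-class label.
#' @return AUC in `[0, 1]`.
#' @export
rankAUC <- function(scores, labels, posClass = "SZ") {
  pos <- labels == posClass
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0L || nn == 0L) stop("both classes required for AUC")
  r <- rank(scores)
  (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
}

reportFrom <- function(y, pred, posClass, protocol, seed, best,
                       features) {
  tp <- sum(pred$class == posClass & y == posClass)
  fn <- sum(pred$class != posClass & y == posClass)
  tn <- sum(pred$class != posClass & y != posClass)
  fp <- sum(pred$class == posClass & y != posClass)
  m <- confusionMetrics(tp, fn, tn, fp)
  structure(list(accuracy = m$accuracy,
                 auc = rankAUC(pred$score, y, posClass),
                 sensitivity = m$sensitivity,
                 specificity = m$specificity,
                 confusion = matrix(c(tp, fn, fp, tn), 2, 2,
                                    dimnames = list(pred = c("pos", "neg"),
                                                    truth = c("pos", "neg"))),
                 bestLearner = best$learner, bestParams = best$params,
                 features = features, protocol = protocol,
                 seed = seed),
            class = "ClassificationReport")
}

#' Hold-out evaluation with Bayesian-optimized model selection
#'
#' Subject-dependent protocol: a stratified random epoch-level split
#' (default 80/20), Bayesian optimization of the classifier on the
#' training split (k-fold CV objective), refit of the incumbent on the
#' whole training split, and metrics on the held-out split. Sensitivity
#' uses the positive class (default the SZ-like group); AUC is the rank
#' statistic of the continuous scores.
#'
#' @param table feature table.
#' @param features feature columns to use.
#' @param testFraction held-out fraction (default 0.2).
#' @param budget,nInit,k,space see [bayesOptimize()].
#' @param seed integer seed.
#' @param posClass positive-class label (default `"SZ"`).
#' @return A `ClassificationReport` (accuracy/sensitivity/specificity in
#'   percent, AUC in `[0,1]`, confusion matrix, incumbent descriptor),
#'   with the optimization trace attached as attribute `trace`.
#' @export
evaluateHoldout <- function(table, features, testFraction = 0.2,
                            budget = 30L, nInit = 2L, k = 5L, seed = 1L,
                            posClass = "SZ", space = learnerPool()) {
  y <- classFactor(table$group, posClass)
  set.seed(as.integer(seed))
  test <- logical(nrow(table))
  for (l in levels(y)) {
    idx <- sample(which(y == l))
    test[idx[seq_len(max(1L, round(testFraction * length(idx))))]] <- TRUE
  }
  if (!all(table(y[test]) > 0) || !all(table(y[!test]) > 0))
    stop("degenerate split: both classes required in train and test")
  opt <- bayesOptimize(table[!test, , drop = FALSE], features,
                       space = space, budget = budget, nInit = nInit,
                       k = k, seed = as.integer(seed) + 1L,
                       posClass = posClass)
  ln <- space[[opt$best$learner]]
  fit <- fitLearner(ln, opt$best$params,
                    as.matrix(table[!test, features, drop = FALSE]),
                    y[!test], seed = as.integer(seed) + 2L)
  pred <- predictLearner(fit, as.matrix(table[test, features, drop = FALSE]))
  rep <- reportFrom(as.character(y[test]), pred, posClass,
                    "subject_dependent", as.integer(seed), opt$best,
                    features)
  attr(rep, "trace") <- opt
  rep
}

#' Leave-one-subject-out evaluation
#'
#' Subject-independent protocol: the classifier configuration is first
#' selected by Bayesian optimization on the full table (or supplied via
#' `config`); then, for each of `min(n_HC, n_SZ)` folds, one subject per
#' group is held out, the incumbent configuration is refit from scratch
#' on the remaining subjects' epochs and evaluated on the held-out
#' subjects' epochs. Metrics are averaged over folds.
#'
#' @param table feature table.
#' @param features feature columns to use.
#' @param budget,k,space see [bayesOptimize()] (used when `config` is
#'   NULL).
#' @param seed integer seed.
#' @param posClass positive-class label.
#' @param config optional preselected configuration, a list with
#'   `learner` (name) and `params`; skips the selection step.
#' @return A `ClassificationReport` with fold-averaged metrics, the
#'   pooled confusion matrix, and per-fold metrics as attribute `folds`.
#' @export
leaveOneSubjectOut <- function(table, features, budget = 30L, k = 5L,
                               seed = 1L, posClass = "SZ",
                               space = learnerPool(), config = NULL) {
  y <- classFactor(table$group, posClass)
  subs <- unique(table[, c("subject_id", "group")])
  neg <- levels(y)[1]
  hcIds <- sort(subs$subject_id[subs$group == neg])
  szIds <- sort(subs$subject_id[subs$group == posClass])
  if (length(hcIds) < 2L || length(szIds) < 2L)
    stop("need at least 2 subjects per group")
  if (is.null(config)) {
    opt <- bayesOptimize(table, features, space = space, budget = budget,
                         k = k, seed = as.integer(seed) + 1L,
                         posClass = posClass)
    config <- opt$best
  }
  ln <- space[[config$learner]]
  nf <- min(length(hcIds), length(szIds))
  folds <- vector("list", nf)
  for (f in seq_len(nf)) {
    testSub <- c(hcIds[f], szIds[f])
    te <- table$subject_id %in% testSub
    fit <- fitLearner(ln, config$params,
                      as.matrix(table[!te, features, drop = FALSE]),
                      y[!te], seed = as.integer(seed) + 10L + f)
    pred <- predictLearner(fit, as.matrix(table[te, features, drop = FALSE]))
    folds[[f]] <- reportFrom(as.character(y[te]), pred, posClass,
                             "leave_one_subject_out",
                             as.integer(seed), config, features)
  }
  conf <- Reduce(`+`, lapply(folds, function(r) r$confusion))
  avg <- function(fld) mean(vapply(folds, function(r) r[[fld]], numeric(1)))
  structure(list(accuracy = avg("accuracy"), auc = avg("auc"),
                 sensitivity = avg("sensitivity"),
                 specificity = avg("specificity"), confusion = conf,
                 bestLearner = config$learner, bestParams = config$params,
                 features = features, protocol = "leave_one_subject_out",
                 seed = as.integer(seed)),
            class = "ClassificationReport", folds = folds)
}

#' Incremental ranked-feature models
#'
#' Evaluates the hold-out protocol on the top-1, top-2, ... top-`kMax`
#' ranked features (model 1 uses only the first-ranked feature, and so
#' on).
#'
#' @param table feature table.
#' @param ranking a `RankedFeatures` data.frame from
#'   [chi2RankFeatures()].
#' @param kMax largest feature-subset size (default 19).
#' @param ... passed to [evaluateHoldout()].
#' @return List of `ClassificationReport`s, ordered by k.
#' @export
incrementalFeatureCurve <- function(table, ranking, kMax = 19L, ...) {
  if (kMax > nrow(ranking))
    stop("kMax exceeds the number of ranked features")
  lapply(seq_len(kMax), function(kk)
    evaluateHoldout(table, ranking$feature[seq_len(kk)], ...))
}

#' @method print ClassificationReport
#' @export
print.ClassificationReport <- function(x, ...) {
  cat(sprintf("ClassificationReport [%s]\n", x$protocol))
  cat(sprintf("  accuracy %.2f%%  AUC %.3f  sensitivity %.2f%%  specificity %.2f%%\n",
              x$accuracy, x$auc, x$sensitivity, x$specificity))
  cat(sprintf("  best learner: %s (%s)\n", x$bestLearner,
              paste(names(x$bestParams),
                    vapply(x$bestParams, function(v)
                      format(v, digits = 3), character(1)),
                    sep = "=", collapse = ", ")))
  cat(sprintf("  features (%d): %s\n", length(x$features),
              paste(utils::head(x$features, 6), collapse = ", ")))
  invisible(x)
}

#' @method print OptimizationTrace
#' @export
print.OptimizationTrace <- function(x, ...) {
  cat(sprintf("OptimizationTrace: %d evaluations, incumbent %s (objective %.4f)\n",
              nrow(x$trace), x$best$learner, x$best$objective))
  invisible(x)
}
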