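# Classifier pool for Bayesian-optimized model selection.
#
# Every learner is described by: a name, a `sample(n)` drawing n random
# hyperparameter configurations (uniform, log-uniform where natural), a
# `fit(params, X, y, seed)` returning a fitted wrapper, and `logCols`
# naming the columns that live on a log scale when encoded for the
# surrogate. X is a numeric matrix; y a two-level factor whose SECOND
# level is the positive class. All wrappers are standardized through
# fitLearner()/predictLearner(): features are centered/scaled on the
# training split, predictions return both a hard class and a continuous
# score oriented toward the positive class.

runifLog <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))
runifLogInt <- function(n, lo, hi) {
  pmin(hi, pmax(lo, as.integer(round(runifLog(n, lo, hi)))))
}

# regularized Gaussian discriminant (linear = pooled covariance,
# quadratic = per-class); covariance shrunk toward the scaled identity
gdaFit <- function(X, y, type, gamma) {
  lv <- levels(y)
  p <- ncol(X)
  mus <- lapply(lv, function(l) colMeans(X[y == l, , drop = FALSE]))
  covs <- lapply(lv, function(l) {
    Xl <- X[y == l, , drop = FALSE]
    if (nrow(Xl) < 2L) diag(p) else stats::cov(Xl)
  })
  if (type == "linear") {
    ns <- table(y)
    Sp <- Reduce(`+`, Map(function(S, n) S * (n - 1), covs,
                          as.list(as.numeric(ns)))) /
      (length(y) - length(lv))
    covs <- rep(list(Sp), length(lv))
  }
  covs <- lapply(covs, function(S) {
    S <- (1 - gamma) * S + gamma * mean(diag(S)) * diag(p)
    S + 1e-8 * mean(diag(S)) * diag(p)
  })
  pri <- as.numeric(table(y)) / length(y)
  list(levels = lv, mus = mus, inv = lapply(covs, solve),
       ldet = vapply(covs, function(S) determinant(S)$modulus, numeric(1)),
       logpri = log(pri))
}

gdaScore <- function(model, X) {
  lg <- vapply(seq_along(model$levels), function(k) {
    d <- sweep(X, 2, model$mus[[k]])
    -0.5 * rowSums((d %*% model$inv[[k]]) * d) -
      0.5 * model$ldet[k] + model$logpri[k]
  }, numeric(nrow(X)))
  if (is.null(dim(lg))) dim(lg) <- c(1L, length(model$levels))
  m <- apply(lg, 1, max)
  pp <- exp(lg - m)
  pp[, 2] / rowSums(pp)          # P(positive = second level)
}

# naive Bayes with per-feature kernel density class-conditionals
kdeNBFit <- function(X, y) {
  lv <- levels(y)
  dens <- lapply(lv, function(l) {
    Xl <- X[y == l, , drop = FALSE]
    lapply(seq_len(ncol(X)), function(j) {
      v <- Xl[, j]
      if (stats::sd(v) == 0) v <- v + stats::rnorm(length(v), 0, 1e-6)
      d <- stats::density(v, n = 512)
      list(x = d$x, y = pmax(d$y, 1e-12))
    })
  })
  list(levels = lv, dens = dens,
       logpri = log(as.numeric(table(y)) / length(y)))
}

kdeNBScore <- function(model, X) {
  ll <- vapply(seq_along(model$levels), function(k) {
    s <- rep(model$logpri[k], nrow(X))
    for (j in seq_len(ncol(X))) {
      d <- model$dens[[k]][[j]]
      s <- s + log(pmax(stats::approx(d$x, d$y, xout = X[, j],
                                      rule = 2)$y, 1e-12))
    }
    s
  }, numeric(nrow(X)))
  if (is.null(dim(ll))) dim(ll) <- c(1L, length(model$levels))
  m <- apply(ll, 1, max)
  pp <- exp(ll - m)
  pp[, 2] / rowSums(pp)
}

# random Fourier feature map for the kernel learner
rffMap <- function(X, W, b) sqrt(2 / ncol(W)) * cos(X %*% W + rep(b, each = nrow(X)))

#' The classifier search space
#'
#' Nine learner families mirroring the usual automatic-selection pool:
#' discriminant, ensemble (bagged trees), kernel (random-Fourier-feature
#' logistic), knn, svm, linear (ridge logistic), naive_bayes, net
#' (one-hidden-layer perceptron) and tree, each with a bounded
#' hyperparameter domain sampled uniformly (log-uniform where natural).
#'
#' @return Named list of learner descriptors used by [bayesOptimize()].
#' @export
learnerPool <- function() {
  list(
    discriminant = list(
      name = "discriminant", logCols = character(0),
      catLevels = list(type = c("linear", "quadratic")),
      sample = function(n) data.frame(
        type = sample(c("linear", "quadratic"), n, replace = TRUE),
        gamma = stats::runif(n, 0, 1), stringsAsFactors = FALSE),
      fit = function(par, X, y, seed) {
        gdaFit(X, y, par$type, par$gamma)
      },
      score = function(model, X, ...) gdaScore(model, X)),
    ensemble = list(
      name = "ensemble", logCols = c("numTrees", "minNode"),
      sample = function(n) data.frame(
        numTrees = runifLogInt(n, 50L, 400L),
        minNode = runifLogInt(n, 1L, 20L)),
      fit = function(par, X, y, seed) {
        df <- data.frame(X, .y = y)
        ranger::ranger(.y ~ ., data = df, probability = TRUE,
                       num.trees = par$numTrees,
                       min.node.size = par$minNode,
                       seed = seed, num.threads = 1)
      },
      score = function(model, X, pos) {
        stats::predict(model, data.frame(X),
                       num.threads = 1)$predictions[, pos]
      }),
    kernel = list(
      name = "kernel", logCols = c("sigma", "lambda"),
      sample = function(n) data.frame(
        sigma = runifLog(n, 0.1, 100), lambda = runifLog(n, 1e-4, 10)),
      fit = function(par, X, y, seed) {
        set.seed(seed)
        D <- 128L
        W <- matrix(stats::rnorm(ncol(X) * D, 0, 1 / par$sigma), ncol(X))
        b <- stats::runif(D, 0, 2 * pi)
        Z <- rffMap(X, W, b)
        fit <- glmnet::glmnet(Z, y, family = "binomial", alpha = 0,
                              lambda = par$lambda)
        list(W = W, b = b, fit = fit)
      },
      score = function(model, X, ...) {
        as.numeric(stats::predict(model$fit, rffMap(X, model$W, model$b),
                                  type = "response"))
      }),
    knn = list(
      name = "knn", logCols = "k",
      sample = function(n) data.frame(k = runifLogInt(n, 1L, 50L)),
      fit = function(par, X, y, seed) {
        list(X = X, y = y, k = min(par$k, nrow(X) - 1L))
      },
      score = function(model, X, ...) {
        pr <- class::knn(model$X, X, model$y, k = model$k, prob = TRUE)
        p <- attr(pr, "prob")
        ifelse(pr == levels(model$y)[2], p, 1 - p)
      }),
    svm = list(
      name = "svm", logCols = c("cost", "gamma"),
      catLevels = list(kernel = c("linear", "radial", "polynomial")),
      sample = function(n) data.frame(
        kernel = sample(c("linear", "radial", "polynomial"), n,
                        replace = TRUE),
        degree = sample(2:3, n, replace = TRUE),
        cost = runifLog(n, 1e-3, 1e3), gamma = runifLog(n, 1e-3, 1e3),
        stringsAsFactors = FALSE),
      fit = function(par, X, y, seed) {
        e1071::svm(X, y, kernel = par$kernel, degree = par$degree,
                   cost = par$cost, gamma = par$gamma, coef0 = 1,
                   scale = FALSE)
      },
      score = function(model, X, ...) {
        pr <- stats::predict(model, X, decision.values = TRUE)
        dv <- attr(pr, "decision.values")
        pos <- model$levels[2]
        # e1071 orients the decision value toward the FIRST class of the
        # colname "a/b"; flip so larger = positive class
        first <- strsplit(colnames(dv)[1], "/")[[1]][1]
        if (first == pos) as.numeric(dv) else -as.numeric(dv)
      }),
    linear = list(
      name = "linear", logCols = "lambda",
      sample = function(n) data.frame(lambda = runifLog(n, 1e-4, 10)),
      fit = function(par, X, y, seed) {
        glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                       lambda = par$lambda)
      },
      score = function(model, X, ...)
        as.numeric(stats::predict(model, X, type = "response"))),
    naive_bayes = list(
      name = "naive_bayes", logCols = character(0),
      catLevels = list(dist = c("gaussian", "kernel")),
      sample = function(n) data.frame(
        dist = sample(c("gaussian", "kernel"), n, replace = TRUE),
        stringsAsFactors = FALSE),
      fit = function(par, X, y, seed) {
        if (par$dist == "gaussian")
          list(dist = "gaussian",
               fit = e1071::naiveBayes(data.frame(X), y), y = y)
        else list(dist = "kernel", fit = kdeNBFit(X, y))
      },
      score = function(model, X, pos) {
        if (model$dist == "gaussian")
          stats::predict(model$fit, data.frame(X), type = "raw")[, pos]
        else kdeNBScore(model$fit, X)
      }),
    net = list(
      name = "net", logCols = c("size", "decay"),
      sample = function(n) data.frame(
        size = runifLogInt(n, 4L, 64L), decay = runifLog(n, 1e-5, 1)),
      fit = function(par, X, y, seed) {
        set.seed(seed)
        df <- data.frame(X, .y = y)
        nnet::nnet(.y ~ ., data = df, size = par$size, decay = par$decay,
                   maxit = 150, trace = FALSE, MaxNWts = 20000)
      },
      score = function(model, X, ...)
        as.numeric(stats::predict(model, data.frame(X), type = "raw"))),
    tree = list(
      name = "tree", logCols = "minBucket",
      sample = function(n) data.frame(minBucket = runifLogInt(n, 1L, 64L)),
      fit = function(par, X, y, seed) {
        df <- data.frame(X, .y = y)
        rpart::rpart(.y ~ ., data = df, cp = 1e-4,
                     minbucket = par$minBucket)
      },
      score = function(model, X, pos)
        stats::predict(model, data.frame(X), type = "prob")[, pos])
  )
}

#' Fit one learner configuration
#'
#' Standardizes the features on the training data (center/scale; a
#' constant feature keeps scale 1) and fits the learner. The positive
#' class is the second level of `y`.
#'
#' @param learner a descriptor from [learnerPool()].
#' @param params one-row data.frame of hyperparameters.
#' @param X numeric training matrix (rows = samples).
#' @param y two-level factor.
#' @param seed integer seed (forwarded to stochastic learners).
#' @return A fitted-model wrapper for [predictLearner()].
#' @export
fitLearner <- function(learner, params, X, y, seed = 1L) {
  X <- as.matrix(X)
  if (nlevels(droplevels(y)) < 2L) stop("training data has a single class")
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, `/`)
  set.seed(as.integer(seed))
  model <- learner$fit(params, Xs, y, as.integer(seed))
  structure(list(learner = learner$name, params = params, model = model,
                 scoreFun = learner$score, center = ctr, scale = scl,
                 levels = levels(y)),
            class = "fittedLearner")
}

#' Predict from a fitted learner
#'
#' @param fit a `fittedLearner` from [fitLearner()].
#' @param X numeric matrix of rows to predict.
#' @return list with `score` (continuous, larger = more positive-class)
#'   and `class` (character labels; score threshold at 0.5 for
#'   probability-like scores, 0 for decision values).
#' @export
predictLearner <- function(fit, X) {
  X <- as.matrix(X)
  Xs <- sweep(sweep(X, 2, fit$center), 2, fit$scale, `/`)
  sc <- fit$scoreFun(fit$model, Xs, fit$levels[2])
  thr <- if (fit$learner == "svm") 0 else 0.5
  cls <- ifelse(sc > thr, fit$levels[2], fit$levels[1])
  list(score = as.numeric(sc), class = cls)
}
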