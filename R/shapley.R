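#' Exact interventional Shapley values
#'
#' Explains a model score at a query point against a background sample.
#' The value of a coalition S is the mean model score over background
#' rows with the query's values substituted on S (the interventional
#' value function); the Shapley value of feature i averages its marginal
#' contribution over all coalitions with the usual combinatorial weights.
#' By local accuracy the contributions sum to
#' `score(query) - mean(score(background))`.
#'
#' Coalitions are enumerated exhaustively for up to `maxExact` features;
#' beyond that a permutation-sampling estimator with `nPerm` random
#' permutations is used (contributions then carry Monte-Carlo error but
#' still satisfy local accuracy on average).
#'
#' @param scoreFun function taking a data.frame/matrix of rows and
#'   returning one numeric score per row.
#' @param query a single row (data.frame or named vector).
#' @param background data.frame of background rows (non-empty).
#' @param maxExact exhaustive-enumeration limit (default 12).
#' @param nPerm permutations for the sampling estimator (default 512).
#' @param seed seed for the sampling estimator.
#' @return Named numeric vector of per-feature contributions, with
#'   attributes `score` (query score) and `baseline` (mean background
#'   score).
#' @export
shapleyValues <- function(scoreFun, query, background, maxExact = 12L,
                          nPerm = 512L, seed = 1L) {
  if (NROW(background) == 0L) stop("background must be non-empty")
  query <- as.data.frame(as.list(query))[names(background)]
  d <- ncol(background)
  nb <- nrow(background)
  if (d <= maxExact) {
    nS <- bitwShiftL(1L, d)
    # rows for all (subset, background) pairs, subset-major
    big <- background[rep(seq_len(nb), nS), , drop = FALSE]
    for (i in seq_len(d)) {
      inS <- bitwAnd(bitwShiftR(seq_len(nS) - 1L, i - 1L), 1L) == 1L
      rows <- rep(inS, each = nb)
      big[rows, i] <- query[[i]]
    }
    sc <- scoreFun(big)
    v <- vapply(seq_len(nS), function(s) mean(sc[((s - 1L) * nb + 1L):(s * nb)]),
                numeric(1))
    masks <- 0:(nS - 1L)
    sizes <- vapply(masks, bitcount, integer(1))   # sizes[k + 1] = |mask k|
    fact <- factorial(0:d)
    phi <- numeric(d)
    for (i in seq_len(d)) {
      bit <- bitwShiftL(1L, i - 1L)
      noI <- masks[bitwAnd(masks, bit) == 0L]
      s <- sizes[noI + 1L]
      w <- fact[s + 1L] * fact[d - s] / fact[d + 1L]
      phi[i] <- sum(w * (v[noI + bit + 1L] - v[noI + 1L]))
    }
  } else {
    set.seed(as.integer(seed))
    phi <- numeric(d)
    base <- scoreFun(background)
    for (p in seq_len(nPerm)) {
      ord <- sample.int(d)
      cur <- background
      prev <- mean(base)
      for (i in ord) {
        cur[, i] <- query[[i]]
        now <- mean(scoreFun(cur))
        phi[i] <- phi[i] + (now - prev)
        prev <- now
      }
    }
    phi <- phi / nPerm
  }
  names(phi) <- names(background)
  attr(phi, "score") <- mean(scoreFun(query))
  attr(phi, "baseline") <- mean(scoreFun(background))
  phi
}

bitcount <- function(x) {
  n <- 0L
  while (x > 0L) { n <- n + bitwAnd(x, 1L); x <- bitwShiftR(x, 1L) }
  n
}

#' Mean-absolute Shapley summary over queries
#'
#' @param scoreFun,background as in [shapleyValues()].
#' @param queries data.frame of query rows.
#' @param ... passed to [shapleyValues()].
#' @return data.frame with per-feature mean |Shapley value|, descending.
#' @export
shapleySummary <- function(scoreFun, queries, background, ...) {
  vals <- t(vapply(seq_len(nrow(queries)), function(i)
    as.numeric(shapleyValues(scoreFun, queries[i, , drop = FALSE],
                             background, ...)),
    numeric(ncol(background))))
  out <- data.frame(feature = names(background),
                    meanAbsShapley = colMeans(abs(vals)))
  out[order(-out$meanAbsShapley), , drop = FALSE]
}
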