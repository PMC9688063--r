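#' Pooled-variance two-sample t-test with Bonferroni flag
#'
#' Student (pooled-variance) two-sample t-test, two-sided; `t > 0` when
#' `mean(x) > mean(y)`. With zero pooled variance and equal means the
#' degenerate result `t = 0, p = 1` is returned.
#'
#' @param x,y numeric samples (each n >= 2).
#' @param m Bonferroni family size (default 20); the significance flag is
#'   `p < alpha / m`.
#' @param alpha base significance level (default 0.05).
#' @return A list with `t`, `p`, `df`, `significant`, and the group
#'   means/SDs.
#' @export
twoSampleTTest <- function(x, y, m = 20L, alpha = 0.05) {
  if (length(x) < 2L || length(y) < 2L) stop("each sample needs n >= 2")
  res <- tryCatch(stats::t.test(x, y, var.equal = TRUE),
                  error = function(e) NULL)
  if (is.null(res)) {            # zero pooled variance
    if (isTRUE(all.equal(mean(x), mean(y))))
      res <- list(statistic = 0, p.value = 1,
                  parameter = length(x) + length(y) - 2L)
    else
      res <- list(statistic = sign(mean(x) - mean(y)) * Inf, p.value = 0,
                  parameter = length(x) + length(y) - 2L)
  }
  list(t = unname(res$statistic), p = unname(res$p.value),
       df = unname(res$parameter), significant = res$p.value < alpha / m,
       meanX = mean(x), sdX = stats::sd(x),
       meanY = mean(y), sdY = stats::sd(y))
}

#' Univariate group comparison of all features
#'
#' Per feature: group means and SDs, pooled-variance t (first group minus
#' second), two-sided p, and the Bonferroni significance flag.
#'
#' @param table a feature table (`group` column plus feature columns).
#' @param groups the two group labels in the order entering the t sign
#'   (default `c("HC", "SZ")`, i.e. `t > 0` when the HC mean is larger).
#' @param m Bonferroni family size (default: number of features).
#' @return A data.frame, one row per feature.
#' @export
univariateTable <- function(table, groups = c("HC", "SZ"), m = NULL) {
  featCols <- setdiff(names(table), c("subject_id", "group", "epoch"))
  if (is.null(m)) m <- length(featCols)
  rows <- lapply(featCols, function(f) {
    r <- twoSampleTTest(table[table$group == groups[1], f],
                        table[table$group == groups[2], f], m = m)
    data.frame(feature = f, mean1 = r$meanX, sd1 = r$sdX,
               mean2 = r$meanY, sd2 = r$sdY, t = r$t, p = r$p,
               significant = r$significant, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[2:5] <- c(paste0("mean_", groups[1]), paste0("sd_", groups[1]),
                       paste0("mean_", groups[2]), paste0("sd_", groups[2]))
  out
}

# equal-frequency discretization; tied breakpoints merged
binEqualFrequency <- function(x, nBins = 10L) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = nBins + 1L),
                               names = FALSE, type = 7))
  if (length(br) < 2L) return(factor(rep(1L, length(x))))
  cut(x, breaks = br, include.lowest = TRUE)
}

#' Chi-square feature ranking
#'
#' Each feature is discretized into equal-frequency bins (tied
#' breakpoints merged) and tested against the class label with a Pearson
#' chi-square test on the bin x class contingency table (no continuity
#' correction). The importance score is `-log10(p)` (computed on the log
#' scale, so arbitrarily small p-values stay finite); features are
#' returned in descending importance, name-ordered within ties. A
#' constant feature collapses to a single bin and scores 0.
#'
#' @param table a feature table (`group` column plus feature columns).
#' @param nBins number of equal-frequency bins (default 10).
#' @return A data.frame of class `RankedFeatures` with columns `feature`,
#'   `statistic`, `df`, `p`, `importance`, sorted by descending
#'   importance.
#' @export
chi2RankFeatures <- function(table, nBins = 10L) {
  cls <- factor(table$group)
  if (nlevels(cls) < 2L) stop("need at least 2 classes")
  if (min(table(cls)) < nBins)
    stop("each class needs at least nBins samples")
  featCols <- setdiff(names(table), c("subject_id", "group", "epoch"))
  rows <- lapply(featCols, function(f) {
    b <- binEqualFrequency(table[[f]], nBins)
    if (nlevels(droplevels(b)) < 2L)
      return(data.frame(feature = f, statistic = 0, df = 0L, p = 1,
                        importance = 0, stringsAsFactors = FALSE))
    tab <- table(droplevels(b), cls)
    st <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    lp <- stats::pchisq(unname(st$statistic), unname(st$parameter),
                        lower.tail = FALSE, log.p = TRUE)
    data.frame(feature = f, statistic = unname(st$statistic),
               df = unname(st$parameter), p = exp(lp),
               importance = -lp / log(10), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$importance, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("RankedFeatures", "data.frame")
  out
}
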