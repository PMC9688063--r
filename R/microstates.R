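#' Global field power
#'
#' GFP at a sample is the spatial standard deviation of the potentials
#' over the N electrodes: `sqrt(sum_i (V_i - Vmean)^2 / N)`.
#'
#' @param x a channels-long numeric vector (one frame) or a
#'   channels x samples matrix (vectorized over columns).
#' @return GFP value(s), in the input's units (microvolts).
#' @examples
#' computeGFP(c(2, 0, 1, 1))  # sqrt(0.5)
#' @export
computeGFP <- function(x) {
  if (is.matrix(x)) {
    if (nrow(x) < 2L) stop("GFP needs at least 2 channels")
    return(sqrt(colMeans(sweep(x, 2, colMeans(x))^2)))
  }
  if (length(x) < 2L) stop("GFP needs at least 2 channels")
  sqrt(mean((x - mean(x))^2))
}

#' Detect local maxima of a GFP series
#'
#' A peak is a sample `i` (excluding the first and last samples) with
#' `g[i-1] < g[i] >= g[i+1]`; the first sample of a plateau gets the
#' credit.
#'
#' @param g numeric GFP series of length >= 3.
#' @return Integer vector of 1-based peak indices.
#' @examples
#' detectGFPPeaks(c(0, 1, 0, 2, 0))  # 2 and 4
#' @export
detectGFPPeaks <- function(g) {
  n <- length(g)
  if (n < 3L) stop("series must have at least 3 samples")
  i <- 2:(n - 1L)
  i[g[i - 1L] < g[i] & g[i] >= g[i + 1L]]
}

#' Spatial correlation between two topographic maps
#'
#' Pearson correlation across channels of the average-referenced maps;
#' by default polarity-invariant (absolute value), the convention for
#' spontaneous EEG microstates.
#'
#' @param map1,map2 numeric vectors of equal length (>= 3 channels),
#'   neither constant.
#' @param polarityInvariant take the absolute value (default TRUE).
#' @return Correlation in `[0, 1]` (or `[-1, 1]` if not invariant).
#' @export
spatialCorrelation <- function(map1, map2, polarityInvariant = TRUE) {
  if (length(map1) != length(map2) || length(map1) < 3L)
    stop("maps must have equal length >= 3")
  a <- map1 - mean(map1); b <- map2 - mean(map2)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("constant map: spatial correlation undefined")
  r <- sum(a * b) / (na * nb)
  if (polarityInvariant) abs(r) else r
}

#' Extract GFP-peak topographies from an epoch or recording
#'
#' @param x a channels x samples matrix, an [EEGRecording-class], or an
#'   [EpochSet-class] (peaks are collected per retained epoch; indices are
#'   within-epoch and therefore only the maps and GFP values should be
#'   pooled across epochs).
#' @return A [PeakSet-class]; maps are average-referenced columns.
#' @export
extractPeakMaps <- function(x) {
  if (is(x, "EEGRecording")) x <- x@data
  if (is(x, "EpochSet")) {
    keep <- which(x@retained)
    spe <- dim(x@epochs)[3]
    parts <- lapply(keep, function(i) extractPeakMaps(epochData(x, i)))
    maps <- do.call(cbind, lapply(parts, peakMaps))
    gfps <- unlist(lapply(parts, peakGFP), use.names = FALSE)
    idx <- unlist(lapply(seq_along(parts), function(j)
      peakIndices(parts[[j]]) + (keep[j] - 1L) * spe), use.names = FALSE)
    return(new("PeakSet", indices = as.integer(idx), maps = maps,
               gfp = gfps))
  }
  g <- computeGFP(x)
  pk <- detectGFPPeaks(g)
  maps <- sweep(x[, pk, drop = FALSE], 2, colMeans(x[, pk, drop = FALSE]))
  new("PeakSet", indices = as.integer(pk), maps = maps, gfp = g[pk])
}

# center columns and scale to unit norm (drop-in for clustering substrate)
normalizeMaps <- function(M) {
  M <- sweep(M, 2, colMeans(M))
  nrm <- sqrt(colSums(M^2))
  nrm[nrm == 0] <- 1
  sweep(M, 2, nrm, `/`)
}

# GEV of an assignment: sum_t (GFP_t r_t)^2 / sum_t GFP_t^2
gevOf <- function(gfp, r) sum((gfp * r)^2) / sum(gfp^2)

# principal eigenvector of M M^T with a deterministic sign
principalMap <- function(M) {
  v <- eigen(tcrossprod(M), symmetric = TRUE)$vectors[, 1]
  v <- v - mean(v)                      # columns of M are centered already;
  v <- v / sqrt(sum(v^2))               # guard against numerical drift
  if (v[which.max(abs(v))] < 0) v <- -v
  v
}

#' Polarity-invariant modified K-means clustering of GFP-peak maps
#'
#' The microstate flavor of K-means: each peak map is assigned to the
#' template with maximal squared spatial correlation (so polarity is
#' ignored), and each template is updated to the principal eigenvector of
#' the outer-product scatter of its assigned raw (average-referenced)
#' maps — equivalently, the GFP-squared-weighted scatter of the
#' normalized maps. With this update the assignment/update alternation
#' is exact coordinate ascent on GEV, so every converged run sits at a
#' local GEV maximum.
#' Convergence is declared when the relative GEV change falls below `tol`
#' or after `maxIter` iterations. The procedure restarts `nRestarts`
#' times from random peak maps; the restart with the highest GEV wins.
#' An emptied cluster is re-seeded from the currently worst-explained
#' peak map. Deterministic given `seed`.
#'
#' @param peaks a [PeakSet-class] with at least `K` peaks.
#' @param K number of microstate classes (default 4).
#' @param nRestarts number of random restarts (default 20).
#' @param tol relative GEV convergence threshold (default 1e-6).
#' @param maxIter maximum iterations per restart (default 1000).
#' @param seed integer seed.
#' @return A list with `templates` (a [TemplateSet-class], labels
#'   `M1..MK`), `assignments` (per-peak template index), and
#'   `correlations` (per-peak absolute spatial correlation with the
#'   assigned template).
#' @export
modifiedKMeans <- function(peaks, K = 4L, nRestarts = 20L, tol = 1e-6,
                           maxIter = 1000L, seed = 1L) {
  P <- ncol(peaks@maps)
  if (P < K) stop("fewer peaks than clusters")
  U <- normalizeMaps(peaks@maps)
  w <- peaks@gfp
  set.seed(as.integer(seed))
  best <- NULL
  # restarts use distinct initial peak subsets where possible, so small
  # instances get broad basin coverage instead of duplicated draws
  seen <- character(0)
  inits <- vector("list", nRestarts)
  for (r in seq_len(nRestarts)) {
    for (att in 1:50) {
      cand <- sort(sample.int(P, K))
      key <- paste(cand, collapse = ",")
      if (!(key %in% seen)) break
    }
    seen <- c(seen, key)
    inits[[r]] <- cand
  }
  for (r in seq_len(nRestarts)) {
    Tm <- U[, inits[[r]], drop = FALSE]
    prevGev <- -Inf
    for (it in seq_len(maxIter)) {
      cors <- crossprod(Tm, U)                       # K x P
      a <- max.col(t(cors^2), ties.method = "first")
      # re-seed empty clusters from the worst-explained peak
      repeat {
        empty <- setdiff(seq_len(K), unique(a))
        if (!length(empty)) break
        rbest <- abs(cors[cbind(a, seq_len(P))])
        worst <- which.min(rbest)
        Tm[, empty[1]] <- U[, worst]
        cors <- crossprod(Tm, U)
        a <- max.col(t(cors^2), ties.method = "first")
      }
      rr <- abs(cors[cbind(a, seq_len(P))])
      gv <- gevOf(w, rr)
      if (is.finite(prevGev) &&
          abs(gv - prevGev) < tol * max(prevGev, .Machine$double.eps)) break
      prevGev <- gv
      for (k in seq_len(K)) {
        sel <- a == k
        Tm[, k] <- principalMap(U[, sel, drop = FALSE] *
                                  rep(w[sel], each = nrow(U)))
      }
    }
    cors <- crossprod(Tm, U)
    a <- max.col(t(cors^2), ties.method = "first")
    rr <- abs(cors[cbind(a, seq_len(P))])
    gv <- gevOf(w, rr)
    if (is.null(best) || gv > best$gev)
      best <- list(Tm = Tm, a = a, r = rr, gev = gv)
  }
  maps <- best$Tm
  colnames(maps) <- paste0("M", seq_len(K))
  rownames(maps) <- rownames(peaks@maps)
  ts <- new("TemplateSet", maps = maps, labels = colnames(maps),
            gev = best$gev, nRestarts = as.integer(nRestarts),
            seed = as.integer(seed))
  list(templates = ts, assignments = best$a, correlations = best$r)
}

#' Global explained variance of a peak labeling
#'
#' `GEV = sum_t (GFP_t * r_t)^2 / sum_t GFP_t^2`, where `r_t` is the
#' spatial correlation of peak map `t` with its assigned template.
#'
#' @param peaks a [PeakSet-class].
#' @param assignments per-peak template index (or label).
#' @param templates a [TemplateSet-class].
#' @return GEV in `[0, 1]`.
#' @export
computeGEV <- function(peaks, assignments, templates) {
  if (length(assignments) != ncol(peaks@maps))
    stop("every peak needs a label")
  if (is.character(assignments))
    assignments <- match(assignments, templates@labels)
  U <- normalizeMaps(peaks@maps)
  r <- abs(colSums(U * templates@maps[, assignments, drop = FALSE]))
  gevOf(peaks@gfp, r)
}

#' Relabel templates against canonical maps
#'
#' Finds, among all 24 permutations (exhaustively), the assignment of the
#' four canonical labels to the four templates maximizing the summed
#' absolute spatial correlation; ties are broken by lexicographic
#' permutation order. Polarity is ignored.
#'
#' @param templates a 4-map [TemplateSet-class].
#' @param canon a 4-map canonical [TemplateSet-class] on the same montage
#'   (e.g. [makeTemplates()]).
#' @return The [TemplateSet-class] with maps reordered and labeled
#'   `A`-`D` per the best permutation.
#' @export
assignCanonicalLabels <- function(templates, canon) {
  if (ncol(templates@maps) != 4L || ncol(canon@maps) != 4L)
    stop("canonical labeling requires K = 4")
  if (nrow(templates@maps) != nrow(canon@maps))
    stop("montage mismatch between templates and canonical maps")
  R <- abs(stats::cor(templates@maps, canon@maps))   # 4 x 4, tpl x canon
  perms <- permutations4()
  scores <- vapply(seq_len(nrow(perms)),
                   function(i) sum(R[cbind(perms[i, ], 1:4)]), numeric(1))
  p <- perms[which.max(scores), ]   # p[j] = template index taking canon label j
  maps <- templates@maps[, p, drop = FALSE]
  colnames(maps) <- canon@labels
  initialize(templates, maps = maps, labels = canon@labels)
}

# all permutations of 1:4 in lexicographic order
permutations4 <- function() {
  out <- matrix(0L, 24L, 4L)
  k <- 0L
  for (a in 1:4) for (b in setdiff(1:4, a)) for (cc in setdiff(1:4, c(a, b))) {
    k <- k + 1L
    out[k, ] <- c(a, b, cc, setdiff(1:4, c(a, b, cc)))
  }
  out
}

#' Backfit template maps to an epoch
#'
#' Each GFP peak of the epoch is labeled by maximal absolute spatial
#' correlation with the template maps; every non-peak sample inherits the
#' label of its nearest peak (the boundary between two consecutive peaks
#' lies at their midpoint; samples before the first and after the last
#' peak take that peak's label).
#'
#' @param epoch a channels x samples matrix (already filtered and
#'   average-referenced).
#' @param templates a [TemplateSet-class].
#' @param fs sampling rate in Hz.
#' @return A [MicrostateSegmentation-class].
#' @export
backfitLabels <- function(epoch, templates, fs) {
  pk <- extractPeakMaps(epoch)
  if (length(pk@indices) == 0L) stop("epoch has no GFP peaks")
  U <- normalizeMaps(pk@maps)
  cors <- crossprod(templates@maps, U)
  a <- max.col(t(cors^2), ties.method = "first")
  r <- abs(cors[cbind(a, seq_along(a))])
  n <- ncol(epoch)
  idx <- pk@indices
  bounds <- c(1L, as.integer(floor((idx[-1] + idx[-length(idx)]) / 2)) + 1L,
              n + 1L)
  lab <- character(n)
  for (j in seq_along(idx))
    lab[bounds[j]:(bounds[j + 1L] - 1L)] <- templates@labels[a[j]]
  new("MicrostateSegmentation", labels = lab, peakIndices = idx,
      peakLabels = templates@labels[a], peakCorrelations = r,
      gev = gevOf(pk@gfp, r), fs = fs)
}
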