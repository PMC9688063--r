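#' @import methods
NULL

#' Electrode montage
#'
#' A named set of scalp electrodes with 2-D head-circle coordinates
#' (unitless, nose up: x grows to the right, y grows to the front).
#'
#' @slot channels character vector of electrode labels (unique).
#' @slot positions numeric matrix (channels x 2) of coordinates inside the
#'   unit circle; rownames equal `channels`.
#' @seealso [standardMontage1020()]
#' @export
setClass("Montage",
  representation(channels = "character", positions = "matrix"))

setValidity("Montage", function(object) {
  msg <- character(0)
  if (anyDuplicated(object@channels))
    msg <- c(msg, "channel names must be unique")
  if (nrow(object@positions) != length(object@channels) ||
      ncol(object@positions) != 2L)
    msg <- c(msg, "positions must be a (channels x 2) matrix")
  if (nrow(object@positions) > 0 &&
      any(sqrt(rowSums(object@positions^2)) > 1 + 1e-8))
    msg <- c(msg, "positions must lie within the unit circle")
  if (length(msg)) msg else TRUE
})

#' Multichannel EEG recording
#'
#' Continuous multichannel potentials for one subject. Values are in
#' microvolts, rows are channels (in montage order), columns are samples.
#'
#' @slot data numeric matrix, channels x samples (microvolts).
#' @slot fs sampling rate in Hz.
#' @slot montage a [Montage-class].
#' @slot subjectId length-1 character.
#' @slot group length-1 character group label (e.g. `"HC"`, `"SZ"`).
#' @export
setClass("EEGRecording",
  representation(data = "matrix", fs = "numeric", montage = "Montage",
                 subjectId = "character", group = "character"))

setValidity("EEGRecording", function(object) {
  msg <- character(0)
  if (anyNA(object@data)) msg <- c(msg, "data must not contain NA")
  if (length(object@fs) != 1L || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (nrow(object@data) != length(object@montage@channels))
    msg <- c(msg, "data rows must match the montage channel count")
  if (length(msg)) msg else TRUE
})

#' Set of fixed-length epochs cut from a recording
#'
#' @slot epochs numeric array, n_epochs x channels x samples_per_epoch;
#'   epochs are nonoverlapping and in temporal order.
#' @slot fs sampling rate in Hz.
#' @slot epochLength epoch length in seconds.
#' @slot retained logical mask, one flag per epoch (FALSE = rejected).
#' @slot montage the recording's [Montage-class].
#' @slot subjectId,group provenance, as in [EEGRecording-class].
#' @export
setClass("EpochSet",
  representation(epochs = "array", fs = "numeric", epochLength = "numeric",
                 retained = "logical", montage = "Montage",
                 subjectId = "character", group = "character"))

setValidity("EpochSet", function(object) {
  d <- dim(object@epochs)
  msg <- character(0)
  if (length(d) != 3L) msg <- c(msg, "epochs must be a 3-D array")
  else {
    if (d[3] != round(object@fs * object@epochLength))
      msg <- c(msg, "third dimension must equal fs * epochLength")
    if (length(object@retained) != d[1])
      msg <- c(msg, "retained mask must have one entry per epoch")
  }
  if (length(msg)) msg else TRUE
})

#' GFP-peak topographies
#'
#' Topographic maps sampled at local maxima of the global field power
#' curve, the substrate of microstate clustering.
#'
#' @slot indices strictly increasing integer sample indices (1-based).
#' @slot maps numeric matrix, channels x peaks; each column is
#'   average-referenced (zero channel mean).
#' @slot gfp numeric vector of GFP values at the peaks (microvolts).
#' @export
setClass("PeakSet",
  representation(indices = "integer", maps = "matrix", gfp = "numeric"))

setValidity("PeakSet", function(object) {
  msg <- character(0)
  if (is.unsorted(object@indices, strictly = TRUE))
    msg <- c(msg, "peak indices must be strictly increasing")
  if (ncol(object@maps) != length(object@indices) ||
      length(object@gfp) != length(object@indices))
    msg <- c(msg, "maps/gfp must have one column/value per peak")
  if (ncol(object@maps) > 0 &&
      max(abs(colMeans(object@maps))) > 1e-6 * max(1, max(abs(object@maps))))
    msg <- c(msg, "peak maps must be average-referenced")
  if (length(msg)) msg else TRUE
})

#' Microstate template maps
#'
#' K unit-norm, average-referenced microstate topographies, together with
#' the GEV they achieved on their clustering substrate.
#'
#' @slot maps numeric matrix, channels x K; columns named by `labels`.
#' @slot labels character state labels (unique; `A`-`D` for K = 4 after
#'   canonical assignment).
#' @slot gev global explained variance achieved on the peak set
#'   (`NA` for constructed template sets).
#' @slot nRestarts,seed clustering restart metadata.
#' @export
setClass("TemplateSet",
  representation(maps = "matrix", labels = "character", gev = "numeric",
                 nRestarts = "integer", seed = "integer"))

setValidity("TemplateSet", function(object) {
  msg <- character(0)
  if (ncol(object@maps) != length(object@labels))
    msg <- c(msg, "one label per template map required")
  if (anyDuplicated(object@labels)) msg <- c(msg, "labels must be unique")
  if (ncol(object@maps) > 0) {
    nrm <- sqrt(colSums(object@maps^2))
    if (any(abs(nrm - 1) > 1e-6))
      msg <- c(msg, "template maps must have unit Euclidean norm")
    if (max(abs(colMeans(object@maps))) > 1e-6)
      msg <- c(msg, "template maps must be average-referenced")
  }
  if (!is.na(object@gev) && (object@gev < -1e-12 || object@gev > 1 + 1e-12))
    msg <- c(msg, "gev must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Microstate segmentation of an epoch
#'
#' Per-sample state labels obtained by backfitting template maps to the
#' GFP peaks of an epoch, plus per-peak assignment detail.
#'
#' @slot labels character vector, one state label per sample.
#' @slot peakIndices integer GFP-peak sample indices (1-based).
#' @slot peakLabels character labels assigned at the peaks.
#' @slot peakCorrelations absolute spatial correlation of each peak map
#'   with its assigned template.
#' @slot gev global explained variance of the assignment over the peaks.
#' @slot fs sampling rate in Hz.
#' @export
setClass("MicrostateSegmentation",
  representation(labels = "character", peakIndices = "integer",
                 peakLabels = "character", peakCorrelations = "numeric",
                 gev = "numeric", fs = "numeric"))

setValidity("MicrostateSegmentation", function(object) {
  msg <- character(0)
  if (length(object@peakIndices) != length(object@peakLabels) ||
      length(object@peakIndices) != length(object@peakCorrelations))
    msg <- c(msg, "per-peak slots must have equal length")
  if (!is.na(object@gev) && (object@gev < -1e-12 || object@gev > 1 + 1e-12))
    msg <- c(msg, "gev must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
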