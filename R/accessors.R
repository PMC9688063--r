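#' Accessors for the core classes
#'
#' Small accessor functions are provided instead of direct slot access:
#' `samplingRate()`, `channelNames()`, `recordingData()`, `subjectId()`,
#' `groupLabel()`, `templateMaps()`, `stateLabels()`, `gev()`,
#' `retainedMask()`, `nEpochs()`, `epochData()`, `peakIndices()`,
#' `peakMaps()`, `peakGFP()`.
#'
#' @param x an object of the documented classes.
#' @param i epoch index for `epochData`.
#' @return The corresponding slot content; `epochData` returns a
#'   channels x samples matrix for one epoch.
#' @name accessors
NULL

#' @rdname accessors
setMethod("samplingRate", "EEGRecording", function(x) x@fs)
#' @rdname accessors
setMethod("samplingRate", "EpochSet", function(x) x@fs)
#' @rdname accessors
setMethod("samplingRate", "MicrostateSegmentation", function(x) x@fs)

#' @rdname accessors
setMethod("channelNames", "Montage", function(x) x@channels)
#' @rdname accessors
setMethod("channelNames", "EEGRecording", function(x) x@montage@channels)
#' @rdname accessors
setMethod("channelNames", "EpochSet", function(x) x@montage@channels)

#' @rdname accessors
setMethod("recordingData", "EEGRecording", function(x) x@data)

#' @rdname accessors
setMethod("subjectId", "EEGRecording", function(x) x@subjectId)
#' @rdname accessors
setMethod("subjectId", "EpochSet", function(x) x@subjectId)

#' @rdname accessors
setMethod("groupLabel", "EEGRecording", function(x) x@group)
#' @rdname accessors
setMethod("groupLabel", "EpochSet", function(x) x@group)

#' @rdname accessors
setMethod("templateMaps", "TemplateSet", function(x) x@maps)

#' @rdname accessors
setMethod("stateLabels", "TemplateSet", function(x) x@labels)
#' @rdname accessors
setMethod("stateLabels", "MicrostateSegmentation", function(x) x@labels)

#' @rdname accessors
setMethod("gev", "TemplateSet", function(x) x@gev)
#' @rdname accessors
setMethod("gev", "MicrostateSegmentation", function(x) x@gev)

#' @rdname accessors
setMethod("retainedMask", "EpochSet", function(x) x@retained)

#' @rdname accessors
setMethod("nEpochs", "EpochSet", function(x) dim(x@epochs)[1])

#' @rdname accessors
setMethod("epochData", "EpochSet", function(x, i) {
  stopifnot(length(i) == 1L, i >= 1L, i <= dim(x@epochs)[1])
  m <- x@epochs[i, , , drop = TRUE]
  dim(m) <- dim(x@epochs)[2:3]
  rownames(m) <- x@montage@channels
  m
})

#' @rdname accessors
setMethod("peakIndices", "PeakSet", function(x) x@indices)
#' @rdname accessors
setMethod("peakIndices", "MicrostateSegmentation", function(x) x@peakIndices)

#' @rdname accessors
setMethod("peakMaps", "PeakSet", function(x) x@maps)

#' @rdname accessors
setMethod("peakGFP", "PeakSet", function(x) x@gfp)

setMethod("show", "Montage", function(object) {
  cat(sprintf("Montage with %d channels: %s\n", length(object@channels),
              paste(utils::head(object@channels, 6), collapse = ", ")))
})

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording '%s' [%s]: %d channels x %d samples @ %g Hz (%.1f s)\n",
              object@subjectId, object@group, nrow(object@data),
              ncol(object@data), object@fs, ncol(object@data) / object@fs))
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@epochs)
  cat(sprintf("EpochSet '%s' [%s]: %d epochs (%d retained) x %d ch x %d samples (%g s @ %g Hz)\n",
              object@subjectId, object@group, d[1], sum(object@retained),
              d[2], d[3], object@epochLength, object@fs))
})

setMethod("show", "PeakSet", function(object) {
  cat(sprintf("PeakSet: %d GFP-peak maps over %d channels\n",
              length(object@indices), nrow(object@maps)))
})

setMethod("show", "TemplateSet", function(object) {
  cat(sprintf("TemplateSet: %d maps (%s) over %d channels; GEV = %s\n",
              ncol(object@maps), paste(object@labels, collapse = ", "),
              nrow(object@maps),
              ifelse(is.na(object@gev), "NA", sprintf("%.3f", object@gev))))
})

setMethod("show", "MicrostateSegmentation", function(object) {
  cat(sprintf("MicrostateSegmentation: %d samples, %d peaks, GEV = %.3f\n",
              length(object@labels), length(object@peakIndices), object@gev))
})
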