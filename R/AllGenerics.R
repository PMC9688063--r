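#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname accessors
#' @export
setGeneric("recordingData", function(x) standardGeneric("recordingData"))

#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname accessors
#' @export
setGeneric("groupLabel", function(x) standardGeneric("groupLabel"))

#' @rdname accessors
#' @export
setGeneric("templateMaps", function(x) standardGeneric("templateMaps"))

#' @rdname accessors
#' @export
setGeneric("stateLabels", function(x) standardGeneric("stateLabels"))

#' @rdname accessors
#' @export
setGeneric("gev", function(x) standardGeneric("gev"))

#' @rdname accessors
#' @export
setGeneric("retainedMask", function(x) standardGeneric("retainedMask"))

#' @rdname accessors
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))

#' @rdname accessors
#' @export
setGeneric("epochData", function(x, i) standardGeneric("epochData"))

#' @rdname accessors
#' @export
setGeneric("peakIndices", function(x) standardGeneric("peakIndices"))

#' @rdname accessors
#' @export
setGeneric("peakMaps", function(x) standardGeneric("peakMaps"))

#' @rdname accessors
#' @export
setGeneric("peakGFP", function(x) standardGeneric("peakGFP"))
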