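#' @name ictalwave-accessors
#' @title Accessors for ictalwave containers
#' @description Slot accessors for [EEGRecording-class], [SegmentSet-class]
#'   and [FuzzyRuleBase-class] objects.
#' @param object an ictalwave container object.
NULL

#' @rdname ictalwave-accessors
#' @export
setGeneric("eegData", function(object) standardGeneric("eegData"))

#' @rdname ictalwave-accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @rdname ictalwave-accessors
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))

#' @rdname ictalwave-accessors
#' @export
setGeneric("annotations", function(object) standardGeneric("annotations"))

#' @rdname ictalwave-accessors
#' @export
setGeneric("segments", function(object) standardGeneric("segments"))

#' @rdname ictalwave-accessors
#' @export
setGeneric("segmentLabels", function(object) standardGeneric("segmentLabels"))

#' @rdname ictalwave-accessors
#' @export
setGeneric("segmentLobes", function(object) standardGeneric("segmentLobes"))

#' @rdname ictalwave-accessors
#' @export
setGeneric("fuzzyRules", function(object) standardGeneric("fuzzyRules"))

#' @rdname ictalwave-accessors
#' @export
setMethod("eegData", "EEGRecording", function(object) object@data)

#' @rdname ictalwave-accessors
#' @export
setMethod("samplingRate", "EEGRecording", function(object) object@samplingRate)

#' @rdname ictalwave-accessors
#' @export
setMethod("samplingRate", "SegmentSet", function(object) object@samplingRate)

#' @rdname ictalwave-accessors
#' @export
setMethod("channelNames", "EEGRecording", function(object) object@channelNames)

#' @rdname ictalwave-accessors
#' @export
setMethod("channelNames", "SegmentSet", function(object) object@channelNames)

#' @rdname ictalwave-accessors
#' @export
setMethod("annotations", "EEGRecording", function(object) object@annotations)

#' @rdname ictalwave-accessors
#' @export
setMethod("segments", "SegmentSet", function(object) object@segments)

#' @rdname ictalwave-accessors
#' @export
setMethod("segmentLabels", "SegmentSet", function(object) object@labels)

#' @rdname ictalwave-accessors
#' @export
setMethod("segmentLobes", "SegmentSet", function(object) object@lobes)

#' @rdname ictalwave-accessors
#' @export
setMethod("fuzzyRules", "FuzzyRuleBase", function(object) object@rules)

#' Number of segments in a SegmentSet
#' @param x a [SegmentSet-class].
#' @return integer count.
#' @export
setMethod("length", "SegmentSet", function(x) length(x@segments))
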