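#' Accessors for Recording and friends
#'
#' @param x a [Recording-class], [LabelSequence-class] or
#'   [SegmentFeatures-class] object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("subjectID", function(x) standardGeneric("subjectID"))

#' @rdname accessors
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' @rdname accessors
#' @export
setGeneric("nFlow", function(x) standardGeneric("nFlow"))

#' @rdname accessors
#' @export
setGeneric("oxSat", function(x) standardGeneric("oxSat"))

#' @rdname accessors
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' @rdname accessors
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))

#' @rdname accessors
#' @export
setGeneric("recordingDuration", function(x) standardGeneric("recordingDuration"))

#' @rdname accessors
#' @export
setGeneric("invalidFraction", function(x) standardGeneric("invalidFraction"))

#' @rdname accessors
setMethod("subjectID", "Recording", function(x) x@subjectID)
#' @rdname accessors
setMethod("sampleRate", "Recording", function(x) x@sampleRate)
#' @rdname accessors
setMethod("nFlow", "Recording", function(x) x@nf)
#' @rdname accessors
setMethod("oxSat", "Recording", function(x) x@spo2)
#' @rdname accessors
setMethod("validMask", "Recording", function(x) x@validMask)
#' @rdname accessors
setMethod("annotations", "Recording", function(x) x@annotations)
#' @rdname accessors
setMethod("recordingDuration", "Recording",
          function(x) length(x@nf) / x@sampleRate)
#' @rdname accessors
setMethod("invalidFraction", "Recording", function(x) mean(!x@validMask))

#' @rdname accessors
setMethod("subjectID", "LabelSequence", function(x) x@subjectID)

#' Segment label sequence as a plain character vector
#'
#' `seqLabels()` returns the per-start-second labels; `seqStarts()` the
#' corresponding start seconds.
#'
#' @param x a [LabelSequence-class].
#' @return character / numeric vector.
#' @export
seqLabels <- function(x) x@labels

#' @rdname seqLabels
#' @export
seqStarts <- function(x) x@startOffset + seq_along(x@labels) - 1L
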