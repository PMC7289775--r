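#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Recording: paired nasal-flow / SpO2 time series
#'
#' The canonical container for one subject's night: a nasal-flow (NF) channel
#' in arbitrary thermistor units and an arterial oxygen saturation (SpO2)
#' channel in percent, both on a common uniform grid (canonically 8 Hz),
#' together with a shared validity mask and the reference respiratory-event
#' annotations.
#'
#' Annotations are stored as a data.frame with columns `onset_s`,
#' `duration_s` and `label`; times are seconds from recording start and event
#' intervals are half-open `[onset, onset + duration)`.
#'
#' @slot subjectID character scalar identifier.
#' @slot sampleRate sampling rate in Hz (canonically 8).
#' @slot nf numeric vector of flow samples.
#' @slot spo2 numeric vector of saturation samples (percent).
#' @slot validMask logical vector, `TRUE` where samples are usable.
#' @slot annotations data.frame of reference respiratory events.
#' @slot metadata free-form list (generator ground truth, provenance).
#'
#' @aliases Recording-class
#' @exportClass Recording
setClass("Recording",
  representation(
    subjectID = "character",
    sampleRate = "numeric",
    nf = "numeric",
    spo2 = "numeric",
    validMask = "logical",
    annotations = "data.frame",
    metadata = "list"
  )
)

setValidity("Recording", function(object) {
  msg <- character()
  n <- length(object@nf)
  if (length(object@spo2) != n || length(object@validMask) != n)
    msg <- c(msg, "nf, spo2 and validMask must have identical length")
  if (length(object@sampleRate) != 1L || !is.finite(object@sampleRate) ||
      object@sampleRate <= 0)
    msg <- c(msg, "sampleRate must be a positive number")
  ann <- object@annotations
  need <- c("onset_s", "duration_s", "label")
  if (!all(need %in% names(ann))) {
    msg <- c(msg, "annotations must have columns onset_s, duration_s, label")
  } else if (nrow(ann) > 0) {
    dur <- n / object@sampleRate
    if (any(ann$duration_s < 0))
      msg <- c(msg, "annotation duration_s must be >= 0")
    if (any(ann$onset_s < 0) || any(ann$onset_s + ann$duration_s > dur + 1e-9))
      msg <- c(msg, "annotations must lie within [0, duration_s)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Recording
#'
#' @param nf numeric vector of nasal-flow samples.
#' @param spo2 numeric vector of SpO2 samples (percent), same length as `nf`.
#' @param sampleRate sampling rate in Hz (default 8).
#' @param subjectID subject identifier.
#' @param validMask logical validity mask; defaults to all `TRUE`.
#' @param annotations data.frame with columns `onset_s`, `duration_s`,
#'   `label`; defaults to none.
#' @param metadata optional list of provenance / ground-truth information.
#' @return A [Recording-class] object.
#' @examples
#' rec <- Recording(nf = sin(2 * pi * 0.25 * seq(0, 60, by = 1 / 8)),
#'                  spo2 = rep(97, 481), subjectID = "demo")
#' recordingDuration(rec)
#' @export
Recording <- function(nf, spo2, sampleRate = 8, subjectID = "anonymous",
                      validMask = NULL, annotations = NULL, metadata = list()) {
  if (is.null(validMask)) validMask <- rep(TRUE, length(nf))
  if (is.null(annotations))
    annotations <- data.frame(onset_s = numeric(), duration_s = numeric(),
                              label = character(), stringsAsFactors = FALSE)
  new("Recording", subjectID = as.character(subjectID),
      sampleRate = as.numeric(sampleRate), nf = as.numeric(nf),
      spo2 = as.numeric(spo2), validMask = as.logical(validMask),
      annotations = annotations, metadata = metadata)
}

#' LabelSequence: per-second predicted classes of 10-s segments
#'
#' One entry per consecutive integer start second; values are `"AH"`, `"N"`
#' or `"UNKNOWN"` (the latter only where the underlying segment was unusable).
#'
#' @slot subjectID character scalar.
#' @slot startOffset integer, the start second of the first entry.
#' @slot windowS the segment window length in seconds (10 for the cascade
#'   output).
#' @slot labels character vector over consecutive start seconds.
#'
#' @aliases LabelSequence-class
#' @exportClass LabelSequence
setClass("LabelSequence",
  representation(
    subjectID = "character",
    startOffset = "integer",
    windowS = "numeric",
    labels = "character"
  )
)

setValidity("LabelSequence", function(object) {
  bad <- setdiff(unique(object@labels), c("AH", "N", "UNKNOWN"))
  if (length(bad))
    return(sprintf("invalid labels: %s", paste(bad, collapse = ", ")))
  if (object@windowS <= 0) return("windowS must be positive")
  TRUE
})

#' Construct a LabelSequence
#'
#' @param labels character vector in `{"AH","N","UNKNOWN"}`.
#' @param startOffset start second of the first entry (default 0).
#' @param windowS window length of the underlying segments (default 10).
#' @param subjectID subject identifier.
#' @return A [LabelSequence-class] object.
#' @export
LabelSequence <- function(labels, startOffset = 0L, windowS = 10,
                          subjectID = "anonymous") {
  new("LabelSequence", subjectID = as.character(subjectID),
      startOffset = as.integer(startOffset), windowS = as.numeric(windowS),
      labels = as.character(labels))
}

#' SegmentFeatures: per-segment morphological feature matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment-class] whose single assay
#' `"features"` holds the 19 morphological features (rows) of every usable
#' segment (columns). `colData` carries the segment bookkeeping: `start_s`,
#' `window_s`, `label`, `usable`, `subject_id` and the per-segment rolling
#' baselines `fb`, `spbm`, `spba`.
#'
#' @aliases SegmentFeatures-class
#' @exportClass SegmentFeatures
setClass("SegmentFeatures", contains = "SummarizedExperiment")

#' CascadeModel: the two-stage segment classifier
#'
#' Holds the 10-tree forest over 60-s segments (reduced feature set: `Fha`,
#' `Fhap`, `Spstd`, `Spran`, `Spdum`, `Spdua`), the 20-tree forest over 10-s
#' segments (all 19 features), the inverse-frequency class weights, the
#' gating rule and the training seed.
#'
#' @slot detector60 fitted ranger forest for 60-s segments.
#' @slot detector10 fitted ranger forest for 10-s segments.
#' @slot features60 character, feature names used by `detector60`.
#' @slot features10 character, feature names used by `detector10`.
#' @slot classWeights60 named numeric class weights used for `detector60`.
#' @slot classWeights10 named numeric class weights used for `detector10`.
#' @slot gating `"contain"` (default) or `"overlap"`.
#' @slot seed integer training seed.
#' @slot trainInfo list of training provenance (counts, hyperparameters).
#'
#' @aliases CascadeModel-class
#' @exportClass CascadeModel
setClass("CascadeModel",
  representation(
    detector60 = "ANY",
    detector10 = "ANY",
    features60 = "character",
    features10 = "character",
    classWeights60 = "numeric",
    classWeights10 = "numeric",
    gating = "character",
    seed = "integer",
    trainInfo = "list"
  )
)

setValidity("CascadeModel", function(object) {
  if (!object@gating %in% c("contain", "overlap"))
    return("gating must be 'contain' or 'overlap'")
  TRUE
})

setMethod("show", "Recording", function(object) {
  n <- length(object@nf)
  cat(sprintf("Recording '%s': %d samples @ %g Hz (%.1f s)\n",
              object@subjectID, n, object@sampleRate,
              n / object@sampleRate))
  cat(sprintf("  invalid samples: %.2f%%; annotated events: %d\n",
              100 * mean(!object@validMask), nrow(object@annotations)))
})

setMethod("show", "LabelSequence", function(object) {
  tab <- table(factor(object@labels, levels = c("AH", "N", "UNKNOWN")))
  cat(sprintf("LabelSequence '%s': %d start seconds from t=%d (window %g s)\n",
              object@subjectID, length(object@labels), object@startOffset,
              object@windowS))
  cat(sprintf("  AH: %d  N: %d  UNKNOWN: %d\n",
              tab[["AH"]], tab[["N"]], tab[["UNKNOWN"]]))
})

setMethod("show", "CascadeModel", function(object) {
  cat("CascadeModel (cascaded random forests)\n")
  cat(sprintf("  60-s screen : %d trees on {%s}\n",
              object@trainInfo$num_trees_60 %||% 10L,
              paste(object@features60, collapse = ", ")))
  cat(sprintf("  10-s stage  : %d trees on %d features\n",
              object@trainInfo$num_trees_10 %||% 20L,
              length(object@features10)))
  cat(sprintf("  gating: %s; seed: %d\n", object@gating, object@seed))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
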