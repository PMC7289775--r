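# End-to-end orchestration: preprocess -> features -> cascade (twofold CV)
# -> event detector -> evaluation, for a list of recordings or a simulated
# cohort, with a serialized manifest for reproducibility.

#' Preprocess and featurize one recording
#'
#' Applies artifact masking, SpO2 alignment, segmentation and labelling for
#' both window sizes, then extracts the feature tables (the flow signal is
#' filtered once and shared).
#'
#' @param rec a [Recording-class] with reference annotations.
#' @param cfg a [preprocessConfig()].
#' @param prominence_frac breath-detection threshold (default 0.05).
#' @return list with `feat60`, `feat10` ([SegmentFeatures-class]),
#'   `segments10` (labelled segment table), `duration_s` and
#'   `invalid_fraction`.
#' @export
prepareRecording <- function(rec, cfg = preprocessConfig(),
                             prominence_frac = 0.05) {
  rec <- suppressMessages(removeArtifacts(rec, cfg))
  rec <- alignSpO2(rec, cfg)
  fnf <- filterNF(nFlow(rec), sampleRate(rec), cfg)
  seg60 <- labelSegments(segmentize(rec, 60, cfg), annotations(rec), cfg)
  seg10 <- labelSegments(segmentize(rec, 10, cfg), annotations(rec), cfg)
  list(feat60 = extractFeatures(rec, seg60, cfg, prominence_frac, fnf),
       feat10 = extractFeatures(rec, seg10, cfg, prominence_frac, fnf),
       segments10 = seg10,
       duration_s = recordingDuration(rec),
       invalid_fraction = invalidFraction(rec))
}

#' Featurize a cohort
#'
#' @param recordings named list of annotated [Recording-class] objects.
#' @param cfg a [preprocessConfig()].
#' @param prominence_frac breath-detection threshold.
#' @return list of [prepareRecording()] outputs, in the input order; the
#'   format [crossvalidate()] consumes.
#' @export
cohortFeatures <- function(recordings, cfg = preprocessConfig(),
                           prominence_frac = 0.05) {
  lapply(recordings, prepareRecording, cfg = cfg,
         prominence_frac = prominence_frac)
}

#' Per-subject results from cross-validated label sequences
#'
#' Corrects each recording's predicted sequence with the run-length rules,
#' derives events, and computes estimated and reference AHI and severity.
#' The AHI denominator is the analysed recording duration (no sleep staging
#' is performed).
#'
#' @param cv output of [crossvalidate()].
#' @param recordings the named recording list the cohort was built from.
#' @return data.frame, one row per subject: event counts, event minutes,
#'   `ahi_est`, `ahi_ref`, `severity_est`, `severity_ref`.
#' @export
subjectResults <- function(cv, recordings) {
  rows <- lapply(names(cv$sequences), function(sid) {
    rec <- recordings[[sid]]
    corrected <- correctSequence(cv$sequences[[sid]])
    ev <- eventsFromSequence(corrected)
    dur <- recordingDuration(rec)
    ann <- annotations(rec)
    data.frame(
      subject_id = sid,
      n_events_est = nrow(ev),
      n_events_ref = nrow(ann),
      event_minutes_est = sum(ev$duration_s) / 60,
      event_minutes_ref = sum(ann$duration_s) / 60,
      ahi_est = computeAHI(ev, dur),
      ahi_ref = computeAHI(ann, dur),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$severity_est <- severityOf(out$ahi_est)
  out$severity_ref <- severityOf(out$ahi_ref)
  out
}

#' Run the full detection pipeline
#'
#' Either simulates a cohort (when `recordings` is `NULL`) or consumes the
#' given annotated recordings, then runs preprocessing, feature extraction,
#' twofold cross-validated cascade classification, event detection and the
#' full evaluation.
#'
#' @param recordings optional named list of annotated [Recording-class]
#'   objects; when `NULL` a cohort is simulated from `severity_mix` and
#'   `synth_cfg`.
#' @param seed master seed for simulation, fold splitting and training.
#' @param cfg a [preprocessConfig()].
#' @param synth_cfg a [synthConfig()] template for simulation.
#' @param severity_mix cohort composition when simulating (default
#'   `c(2, 12, 5, 5)`).
#' @param split,gating cross-validation and gating options (see
#'   [crossvalidate()]).
#' @return list with `subjects` (per-subject results), `segment_confusion`,
#'   `segment_metrics`, `ahi_agreement`, `severity_matrix`,
#'   `severity_report` and `manifest`.
#' @export
runPipeline <- function(recordings = NULL, seed = 1L,
                        cfg = preprocessConfig(),
                        synth_cfg = synthConfig(),
                        severity_mix = c(2, 12, 5, 5),
                        split = "segment", gating = "contain") {
  simulated <- is.null(recordings)
  if (simulated)
    recordings <- generateCohort(severity_mix, seed = seed, cfg = synth_cfg)
  if (length(recordings) < 2)
    stop("pipeline needs at least two recordings for cross-validation")
  cohort <- cohortFeatures(recordings, cfg)
  cv <- crossvalidate(cohort, seed = seed, split = split, gating = gating)
  subjects <- subjectResults(cv, recordings)
  sm <- severityMatrix(subjects$severity_est, subjects$severity_ref)
  list(
    subjects = subjects,
    segment_confusion = cv$confusion,
    segment_metrics = segmentMetrics(cv$confusion),
    ahi_agreement = ahiAgreement(subjects$ahi_est, subjects$ahi_ref),
    severity_matrix = sm,
    severity_report = severityReport(sm),
    sequences = cv$sequences,
    manifest = list(
      seed = seed, simulated = simulated, split = split, gating = gating,
      severity_mix = if (simulated) severity_mix else NULL,
      n_recordings = length(recordings),
      preprocess = unclass(cfg),
      synth = if (simulated) unclass(synth_cfg) else NULL,
      package_version = as.character(utils::packageVersion("AHcascade"))
    )
  )
}

#' Read a pipeline configuration file
#'
#' YAML (or JSON) file with optional blocks `preprocess` and `synthetic`
#' whose keys mirror [preprocessConfig()] / [synthConfig()] argument names,
#' plus optional top-level `seed`, `split`, `gating`, `severity_mix`.
#'
#' @param path config file path.
#' @return list with `cfg`, `synth_cfg`, `seed`, `split`, `gating`,
#'   `severity_mix`.
#' @export
readRunConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  pp <- do.call(preprocessConfig, raw$preprocess %||% list())
  sy <- do.call(synthConfig, raw$synthetic %||% list())
  list(cfg = pp, synth_cfg = sy,
       seed = as.integer(raw$seed %||% 1L),
       split = raw$split %||% "segment",
       gating = raw$gating %||% "contain",
       severity_mix = raw$severity_mix %||% c(2, 12, 5, 5))
}

#' Write an evaluation report as JSON
#'
#' @param result output of [runPipeline()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeReport <- function(result, path) {
  out <- list(
    segment_confusion = result$segment_confusion,
    segment_metrics = result$segment_metrics,
    ahi_agreement = result$ahi_agreement,
    severity_matrix = as.data.frame(result$severity_matrix),
    severity_report = list(
      per_cutoff = result$severity_report$per_cutoff,
      means = as.list(result$severity_report$means),
      kappa = result$severity_report$kappa
    ),
    subjects = result$subjects,
    manifest = result$manifest
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
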