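# Signal conditioning ahead of feature extraction: SpO2 artifact masking,
# NF moving-average + high-pass filtering, sliding-window segmentation with
# reference labelling, and the SpO2 time advance that compensates the
# circulatory delay between an airflow event and its desaturation.

#' Preprocessing configuration
#'
#' All thresholds of the preprocessing stage in one validated list.
#'
#' @param spo2_artifact_floor SpO2 percent below which a sample is an
#'   oximeter artifact (default 50).
#' @param ma_points length of the sliding-average filter (default 4).
#' @param ma_centered centre the moving average instead of the causal
#'   default.
#' @param hp_order order of the Butterworth high-pass (default 3).
#' @param hp_cutoff_hz high-pass cutoff in Hz (default 0.05).
#' @param tau_s SpO2 time advance in seconds, must satisfy 0 < tau < 30
#'   (default 23).
#' @param step_s sliding-window step in seconds (default 1).
#' @param ah_overlap_s seconds of event overlap beyond which a segment is
#'   labelled AH (strictly greater than; default 5).
#' @param max_invalid_frac fraction of invalid samples above which a segment
#'   is unusable (default 0.1).
#' @return A classed list (`"PreprocessConfig"`).
#' @export
preprocessConfig <- function(spo2_artifact_floor = 50, ma_points = 4,
                             ma_centered = FALSE, hp_order = 3,
                             hp_cutoff_hz = 0.05, tau_s = 23, step_s = 1,
                             ah_overlap_s = 5, max_invalid_frac = 0.1) {
  if (!(tau_s > 0 && tau_s < 30))
    stop("tau_s must satisfy 0 < tau_s < 30")
  if (ma_points < 1 || step_s < 1)
    stop("ma_points and step_s must be positive integers")
  structure(list(
    spo2_artifact_floor = spo2_artifact_floor, ma_points = as.integer(ma_points),
    ma_centered = isTRUE(ma_centered), hp_order = as.integer(hp_order),
    hp_cutoff_hz = hp_cutoff_hz, tau_s = as.integer(tau_s),
    step_s = as.integer(step_s), ah_overlap_s = ah_overlap_s,
    max_invalid_frac = max_invalid_frac
  ), class = "PreprocessConfig")
}

#' Mask SpO2 artifacts
#'
#' Oximeter dropouts read implausibly low; any SpO2 sample below the
#' artifact floor is marked invalid in the shared validity mask. Sample
#' values themselves are untouched so the time axis stays aligned.
#'
#' @param rec a [Recording-class].
#' @param cfg a [preprocessConfig()].
#' @return The recording with an updated validity mask; the invalid fraction
#'   is reported via `message()`.
#' @export
removeArtifacts <- function(rec, cfg = preprocessConfig()) {
  bad <- oxSat(rec) < cfg$spo2_artifact_floor
  rec@validMask <- rec@validMask & !bad
  message(sprintf("removeArtifacts: %.2f%% of samples marked invalid",
                  100 * mean(!rec@validMask)))
  rec
}

#' Filter the nasal-flow signal
#'
#' A `ma_points`-point sliding average (causal by default) suppresses
#' high-frequency artifact noise, then a Butterworth high-pass of order
#' `hp_order` with cutoff `hp_cutoff_hz` removes baseline drift. The
#' high-pass is applied forward-backward (zero phase) so event timing is not
#' delayed.
#'
#' The minimum input length is three times the high-pass filter order plus
#' one (the `filtfilt` warm-up).
#'
#' @param nf numeric vector of flow samples.
#' @param sample_rate_hz sampling rate in Hz (default 8).
#' @param cfg a [preprocessConfig()].
#' @return The filtered signal, same length as the input.
#' @export
filterNF <- function(nf, sample_rate_hz = 8, cfg = preprocessConfig()) {
  minlen <- 3 * (cfg$hp_order + 1)
  if (length(nf) < minlen)
    stop("input shorter than filter warm-up (", minlen, " samples)")
  k <- cfg$ma_points
  sides <- if (cfg$ma_centered) 2 else 1
  sm <- as.numeric(stats::filter(nf, rep(1 / k, k), sides = sides))
  # stats::filter leaves NAs in the warm-up region; hold the first value
  sm[is.na(sm)] <- sm[which(!is.na(sm))[1]]
  bf <- signal::butter(cfg$hp_order, cfg$hp_cutoff_hz / (sample_rate_hz / 2),
                       type = "high")
  # forward-backward pass with odd-reflection padding so both ends are free
  # of the IIR edge transient (~1/cutoff seconds)
  n <- length(sm)
  pad <- min(n - 1, ceiling(3 / cfg$hp_cutoff_hz * sample_rate_hz))
  xp <- c(2 * sm[1] - sm[pad + 1 - seq_len(pad) + 1],
          sm,
          2 * sm[n] - sm[n - seq_len(pad)])
  yp <- as.numeric(signal::filter(bf, xp))
  yp <- rev(as.numeric(signal::filter(bf, rev(yp))))
  yp[(pad + 1):(pad + n)]
}

#' Advance the SpO2 channel in time
#'
#' Desaturation trails the airflow signature of an event by roughly the
#' lung-to-finger circulation time. Advancing SpO2 (and its validity mask)
#' by `tau_s` seconds makes the two signatures co-occur; the trailing
#' `tau_s` seconds, for which no future SpO2 exists, are marked invalid.
#'
#' @param rec a [Recording-class].
#' @param cfg a [preprocessConfig()] (`tau_s` default 23).
#' @return The recording with shifted SpO2/mask.
#' @export
alignSpO2 <- function(rec, cfg = preprocessConfig()) {
  shift <- as.integer(round(cfg$tau_s * sampleRate(rec)))
  n <- length(oxSat(rec))
  if (n <= shift) stop("recording shorter than tau_s")
  idx <- (shift + 1):n
  sp <- rec@spo2
  vm <- rec@validMask
  rec@spo2 <- c(sp[idx], rep(sp[n], shift))
  rec@validMask <- c(vm[idx], rep(FALSE, shift))
  rec
}

#' Cut a recording into overlapping fixed-length segments
#'
#' One segment per integer start second from 0 to `floor(duration) -
#' window_s`, stepping by `step_s` (canonically 1 s). Segments whose window
#' contains more than `max_invalid_frac` invalid samples are flagged
#' unusable.
#'
#' @param rec a [Recording-class].
#' @param window_s window length in seconds (10 or 60).
#' @param cfg a [preprocessConfig()].
#' @return data.frame with columns `start_s`, `window_s`, `usable`, `label`
#'   (initially `NA`).
#' @export
segmentize <- function(rec, window_s, cfg = preprocessConfig()) {
  if (!window_s %in% c(10, 60))
    warning("window_s of ", window_s, " is non-canonical (expected 10 or 60)")
  dur <- floor(recordingDuration(rec))
  if (dur < window_s) {
    warning("recording shorter than the window; no segments")
    return(data.frame(start_s = integer(), window_s = integer(),
                      usable = logical(), label = character()))
  }
  starts <- seq.int(0L, dur - window_s, by = cfg$step_s)
  fs <- sampleRate(rec)
  w <- as.integer(round(window_s * fs))
  cs <- c(0, cumsum(!validMask(rec)))
  i0 <- as.integer(round(starts * fs))
  invalid <- (cs[i0 + w + 1] - cs[i0 + 1]) / w
  data.frame(start_s = as.integer(starts),
             window_s = as.integer(window_s),
             usable = invalid <= cfg$max_invalid_frac,
             label = NA_character_)
}

#' Label segments from reference annotations
#'
#' A segment is labelled `"AH"` when its overlap with the union of annotated
#' events strictly exceeds `ah_overlap_s` (default 5 s); otherwise `"N"`.
#' Overlap is computed on the union so that abutting or overlapping
#' annotations are not double counted.
#'
#' @param segments data.frame from [segmentize()].
#' @param ann data.frame of events (`onset_s`, `duration_s`, `label`), or a
#'   [Recording-class] whose annotations are used.
#' @param cfg a [preprocessConfig()].
#' @param exclude character vector of annotation labels that do not count as
#'   AH events (default none: the apnea and hypopnea classes are pooled).
#' @return The segments data.frame with `label` filled in.
#' @export
labelSegments <- function(segments, ann, cfg = preprocessConfig(),
                          exclude = character()) {
  if (is(ann, "Recording")) ann <- annotations(ann)
  if (nrow(segments) == 0) return(segments)
  keep <- !(ann$label %in% exclude)
  iv <- mergeIntervals(ann$onset_s[keep], ann$onset_s[keep] + ann$duration_s[keep])
  ov <- overlapWithUnion(segments$start_s, segments$start_s + segments$window_s, iv)
  segments$label <- ifelse(ov > cfg$ah_overlap_s, "AH", "N")
  segments
}

# merge [lo, hi) intervals into a disjoint sorted union
mergeIntervals <- function(lo, hi) {
  keep <- hi > lo
  lo <- lo[keep]; hi <- hi[keep]
  if (length(lo) == 0)
    return(matrix(numeric(0), ncol = 2))
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]
  mlo <- lo[1]; mhi <- hi[1]
  outLo <- numeric(0); outHi <- numeric(0)
  for (i in seq_along(lo)[-1]) {
    if (lo[i] <= mhi) {
      mhi <- max(mhi, hi[i])
    } else {
      outLo <- c(outLo, mlo); outHi <- c(outHi, mhi)
      mlo <- lo[i]; mhi <- hi[i]
    }
  }
  cbind(c(outLo, mlo), c(outHi, mhi))
}

# total overlap of each query interval [qlo, qhi) with a disjoint union
overlapWithUnion <- function(qlo, qhi, iv) {
  if (nrow(iv) == 0) return(numeric(length(qlo)))
  vapply(seq_along(qlo), function(i) {
    sum(pmax(0, pmin(qhi[i], iv[, 2]) - pmax(qlo[i], iv[, 1])))
  }, numeric(1))
}
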