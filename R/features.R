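# The 19 morphological features computed per segment: ten describing the
# nasal-flow breath amplitudes (against a 30-s rolling tidal-volume
# baseline) and nine describing the SpO2 excursion (against 30-s rolling
# maximum/mean saturation baselines).

#' Canonical feature names
#'
#' The 19 per-segment features, in canonical order: `Fmean`, `Fstd`, `Fran`
#' (tidal-volume mean/SD/range), `Fha`/`Fhap` (count and fraction of breaths
#' dropping more than 30% below the rolling baseline), `Fap`/`Fapp` (more
#' than 70%), `Fnor`/`Fnorp` (breaths above 85% of baseline), `Fkur`
#' (fourth standardized moment of the 0.2-0.4 Hz spectral magnitudes),
#' `Spstd`, `Spran`, `Spten` (SpO2 SD, range, last-minus-first), `Sp92`,
#' `Sp91` (seconds below 92%/91%), `Spdum`/`Spdua` (seconds below 98% of the
#' rolling max / mean baseline), `Spldm`/`Splda` (desaturation level:
#' baseline minus segment mean).
#'
#' @return character vector of length 19.
#' @export
featureNames <- function() {
  c("Fmean", "Fstd", "Fran", "Fha", "Fhap", "Fap", "Fapp", "Fnor", "Fnorp",
    "Fkur", "Spstd", "Spran", "Spten", "Sp92", "Sp91", "Spdum", "Spdua",
    "Spldm", "Splda")
}

#' Reduced feature set of the 60-s screening detector
#'
#' The breath-drop counts and the SpO2 dispersion/desaturation-duration
#' pairs; the screen deliberately ignores the remaining features to keep
#' training fast.
#'
#' @return character vector of length 6.
#' @export
screenFeatureNames <- function() {
  c("Fha", "Fhap", "Spstd", "Spran", "Spdum", "Spdua")
}

#' Detect breaths in a filtered nasal-flow signal
#'
#' Scans for alternating maxima and minima whose swing exceeds
#' `prominence_frac` of the overall signal range; each successive
#' (disjoint) pair of extrema is one breath whose tidal volume `Ft` is the
#' difference between the two extreme values.
#'
#' @param nf filtered (zero-mean) flow samples.
#' @param sample_rate_hz sampling rate in Hz.
#' @param prominence_frac minimum swing as a fraction of the signal range
#'   (default 0.05).
#' @return data.frame with one row per breath: `t_max_s`, `t_min_s`,
#'   `t_mid_s`, `tidal_volume`. A flat signal yields zero rows.
#' @export
detectBreaths <- function(nf, sample_rate_hz = 8, prominence_frac = 0.05) {
  rng <- max(nf) - min(nf)
  empty <- data.frame(t_max_s = numeric(), t_min_s = numeric(),
                      t_mid_s = numeric(), tidal_volume = numeric())
  if (rng <= 0) return(empty)
  thr <- prominence_frac * rng
  ext <- alternatingExtrema(nf, thr)
  ne <- nrow(ext)
  if (ne < 2) return(empty)
  np <- ne %/% 2
  i1 <- ext$idx[2 * seq_len(np) - 1]; v1 <- ext$val[2 * seq_len(np) - 1]
  i2 <- ext$idx[2 * seq_len(np)];     v2 <- ext$val[2 * seq_len(np)]
  isMax1 <- v1 >= v2
  tm <- ifelse(isMax1, i1, i2); tn <- ifelse(isMax1, i2, i1)
  data.frame(
    t_max_s = (tm - 1) / sample_rate_hz,
    t_min_s = (tn - 1) / sample_rate_hz,
    t_mid_s = (i1 + i2 - 2) / (2 * sample_rate_hz),
    tidal_volume = abs(v1 - v2)
  )
}

# threshold-crossing peak/valley scan: emits alternating extrema whose
# swing to the next emitted extremum is at least thr
alternatingExtrema <- function(x, thr) {
  n <- length(x)
  idx <- integer(0); val <- numeric(0)
  mx <- -Inf; mn <- Inf; mxpos <- 1L; mnpos <- 1L
  lookForMax <- NA
  for (i in seq_len(n)) {
    v <- x[i]
    if (v > mx) { mx <- v; mxpos <- i }
    if (v < mn) { mn <- v; mnpos <- i }
    if (is.na(lookForMax)) {
      # decide the search direction at the first decisive swing; the
      # running extremum before it is tracked but not emitted, so breaths
      # always start at a genuine peak or trough
      if (v < mx - thr) lookForMax <- FALSE
      else if (v > mn + thr) lookForMax <- TRUE
    } else if (lookForMax) {
      if (v < mx - thr) {
        idx <- c(idx, mxpos); val <- c(val, mx)
        mn <- v; mnpos <- i; lookForMax <- FALSE
      }
    } else {
      if (v > mn + thr) {
        idx <- c(idx, mnpos); val <- c(val, mn)
        mx <- v; mxpos <- i; lookForMax <- TRUE
      }
    }
  }
  data.frame(idx = idx, val = val)
}

#' Rolling baselines for one segment
#'
#' The tidal-volume baseline `Fb` is the maximum breath amplitude over the
#' 30 s preceding the segment; `Spbm`/`Spba` are the maximum and mean valid
#' SpO2 over the same interval. At recording start (or when the lookback
#' holds no breaths / no valid samples) the within-segment values are used
#' as a documented fallback.
#'
#' @param breaths data.frame from [detectBreaths()] (whole recording).
#' @param spo2 full SpO2 sample vector.
#' @param valid full validity mask.
#' @param segment_start_s segment start in seconds.
#' @param window_s segment window length in seconds.
#' @param sample_rate_hz sampling rate in Hz.
#' @param lookback_s baseline lookback (default 30).
#' @return list with `fb`, `spbm`, `spba`.
#' @export
rollingBaselines <- function(breaths, spo2, valid, segment_start_s, window_s,
                             sample_rate_hz = 8, lookback_s = 30) {
  s <- segment_start_s
  inWin <- function(t, lo, hi) t >= lo & t < hi
  ft <- breaths$tidal_volume[inWin(breaths$t_mid_s, s - lookback_s, s)]
  if (length(ft) == 0)
    ft <- breaths$tidal_volume[inWin(breaths$t_mid_s, s, s + window_s)]
  fb <- if (length(ft)) max(ft) else 0

  i0 <- max(0L, as.integer(round((s - lookback_s) * sample_rate_hz)))
  i1 <- as.integer(round(s * sample_rate_hz))
  sl <- if (i1 > i0) (i0 + 1):i1 else integer(0)
  sp <- spo2[sl][valid[sl]]
  if (length(sp) == 0) {
    j1 <- min(length(spo2), as.integer(round((s + window_s) * sample_rate_hz)))
    sl <- if (j1 > i1) (i1 + 1):j1 else integer(0)
    sp <- spo2[sl][valid[sl]]
  }
  if (length(sp) == 0) return(list(fb = fb, spbm = 0, spba = 0))
  list(fb = fb, spbm = max(sp), spba = mean(sp))
}

#' Nasal-flow features of one segment
#'
#' @param ft tidal volumes of the breaths inside the segment.
#' @param nf_seg the segment's filtered flow samples.
#' @param fb tidal-volume baseline from [rollingBaselines()].
#' @param sample_rate_hz sampling rate in Hz.
#' @return named numeric vector of the 10 NF features. With no breaths the
#'   documented default is all zeros (never missing values).
#' @export
nfFeatures <- function(ft, nf_seg, fb, sample_rate_hz = 8) {
  out <- c(Fmean = 0, Fstd = 0, Fran = 0, Fha = 0, Fhap = 0, Fap = 0,
           Fapp = 0, Fnor = 0, Fnorp = 0, Fkur = 0)
  nb <- length(ft)
  if (nb > 0) {
    out["Fmean"] <- mean(ft)
    out["Fstd"] <- if (nb > 1) stats::sd(ft) else 0
    out["Fran"] <- max(ft) - min(ft)
    fha <- sum(ft < 0.7 * fb)
    fap <- sum(ft < 0.3 * fb)
    fnor <- sum(ft > 0.85 * fb)
    out["Fha"] <- fha; out["Fhap"] <- fha / nb
    out["Fap"] <- fap; out["Fapp"] <- fap / nb
    out["Fnor"] <- fnor; out["Fnorp"] <- fnor / nb
  }
  out["Fkur"] <- bandKurtosis(nf_seg, sample_rate_hz)
  out
}

# fourth standardized moment of the magnitude-spectrum values in 0.2-0.4 Hz;
# scale-invariant because the moment is standardized
bandKurtosis <- function(x, fs, band = c(0.2, 0.4)) {
  n <- length(x)
  if (n < 4) return(0)
  m <- Mod(stats::fft(x - mean(x)))
  freq <- (seq_len(n) - 1) * fs / n
  v <- m[freq >= band[1] & freq <= band[2]]
  if (length(v) < 2) return(0)
  ctr <- v - mean(v)
  s2 <- mean(ctr^2)
  if (s2 <= 0) return(0)
  mean(ctr^4) / s2^2
}

#' SpO2 features of one segment
#'
#' Only valid samples contribute; a segment with no valid SpO2 yields the
#' documented all-zero default.
#'
#' @param sp_seg the segment's (aligned) SpO2 samples.
#' @param valid_seg validity mask for the same samples.
#' @param spbm,spba rolling baselines from [rollingBaselines()].
#' @param sample_rate_hz sampling rate in Hz.
#' @return named numeric vector of the 9 SpO2 features; durations are in
#'   seconds (sample count / rate).
#' @export
spo2Features <- function(sp_seg, valid_seg, spbm, spba, sample_rate_hz = 8) {
  sp <- sp_seg[valid_seg]
  if (length(sp) == 0)
    return(c(Spstd = 0, Spran = 0, Spten = 0, Sp92 = 0, Sp91 = 0,
             Spdum = 0, Spdua = 0, Spldm = 0, Splda = 0))
  c(Spstd = if (length(sp) > 1) stats::sd(sp) else 0,
    Spran = max(sp) - min(sp),
    Spten = sp[length(sp)] - sp[1],
    Sp92 = sum(sp < 92) / sample_rate_hz,
    Sp91 = sum(sp < 91) / sample_rate_hz,
    Spdum = sum(sp < 0.98 * spbm) / sample_rate_hz,
    Spdua = sum(sp < 0.98 * spba) / sample_rate_hz,
    Spldm = spbm - mean(sp),
    Splda = spba - mean(sp))
}

#' Extract the full feature table of a recording
#'
#' Orchestrates breath detection (once over the whole filtered flow signal),
#' rolling baselines and the per-segment NF/SpO2 features for every usable
#' segment. Deterministic given its inputs.
#'
#' @param rec a preprocessed [Recording-class] (artifacts masked, SpO2
#'   aligned).
#' @param segments labelled data.frame from [segmentize()] +
#'   [labelSegments()].
#' @param cfg a [preprocessConfig()].
#' @param prominence_frac breath-detection prominence threshold (default
#'   0.05 of the signal range).
#' @param filtered_nf optionally the pre-filtered flow signal (to avoid
#'   re-filtering when extracting both window sizes).
#' @return A [SegmentFeatures-class] with one column per usable segment.
#' @export
extractFeatures <- function(rec, segments, cfg = preprocessConfig(),
                            prominence_frac = 0.05, filtered_nf = NULL) {
  fs <- sampleRate(rec)
  if (is.null(filtered_nf)) filtered_nf <- filterNF(nFlow(rec), fs, cfg)
  breaths <- detectBreaths(filtered_nf, fs, prominence_frac)
  spo2 <- oxSat(rec)
  valid <- validMask(rec)
  use <- which(segments$usable)
  nm <- featureNames()
  mat <- matrix(0, nrow = length(nm), ncol = length(use),
                dimnames = list(nm, NULL))
  fb <- spbm <- spba <- numeric(length(use))

  bt <- breaths$t_mid_s
  bv <- breaths$tidal_volume
  for (k in seq_along(use)) {
    i <- use[k]
    s <- segments$start_s[i]
    w <- segments$window_s[i]
    bl <- rollingBaselines(breaths, spo2, valid, s, w, fs)
    fb[k] <- bl$fb; spbm[k] <- bl$spbm; spba[k] <- bl$spba
    ft <- bv[bt >= s & bt < s + w]
    i0 <- as.integer(round(s * fs)); i1 <- as.integer(round((s + w) * fs))
    sl <- (i0 + 1):min(i1, length(spo2))
    mat[1:10, k] <- nfFeatures(ft, filtered_nf[sl], bl$fb, fs)
    mat[11:19, k] <- spo2Features(spo2[sl], valid[sl], bl$spbm, bl$spba, fs)
  }

  cd <- S4Vectors::DataFrame(
    start_s = segments$start_s[use],
    window_s = segments$window_s[use],
    label = segments$label[use],
    usable = rep(TRUE, length(use)),
    subject_id = rep(subjectID(rec), length(use)),
    fb = fb, spbm = spbm, spba = spba
  )
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = mat), colData = cd)
  colnames(se) <- sprintf("%s_w%d_t%d", subjectID(rec),
                          segments$window_s[use], segments$start_s[use])
  new("SegmentFeatures", se)
}

#' Feature table as a plain data.frame
#'
#' Columns `start_s`, `window_s`, `label`, `usable`, `subject_id` followed
#' by the 19 features (canonical names as headers); the layout written by
#' [writeFeatureTable()].
#'
#' @param sf a [SegmentFeatures-class].
#' @return data.frame, one row per segment.
#' @export
featureFrame <- function(sf) {
  cd <- as.data.frame(SummarizedExperiment::colData(sf))
  keep <- c("start_s", "window_s", "label", "usable", "subject_id")
  ft <- t(SummarizedExperiment::assay(sf, "features"))
  out <- cbind(cd[keep], as.data.frame(ft))
  rownames(out) <- NULL
  out
}

#' Write / read a feature table as CSV
#'
#' @param sf a [SegmentFeatures-class].
#' @param path output path.
#' @return `path` invisibly ([writeFeatureTable()]); a data.frame in the
#'   [featureFrame()] layout ([readFeatureTable()]).
#' @export
writeFeatureTable <- function(sf, path) {
  utils::write.csv(featureFrame(sf), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(featureNames(), names(df))
  if (length(miss))
    stop("feature table missing columns: ", paste(miss, collapse = ", "))
  df
}
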