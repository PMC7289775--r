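# Synthetic polysomnography: annotated nasal-flow + SpO2 recordings with
# the morphology the detector assumes — amplitude-modulated breathing,
# renewal-scheduled apneas/hypopneas (>=10 s, flow drop scaled by a
# residual fraction), lagged quantized desaturations, baseline drift below
# the high-pass band, and oximeter dropout artifacts.

#' Synthetic recording configuration
#'
#' Defaults are the package's standing study conditions; see the methods
#' vignette for the rationale behind each value.
#'
#' @param duration_s recording length in seconds (default 3600).
#' @param target_ahi target event rate, events/h (default 15).
#' @param apnea_fraction proportion of events that are apneas (default
#'   0.5); the rest are hypopneas.
#' @param resp_freq_hz mean breathing frequency (default 0.25, one breath
#'   per 3-5 s).
#' @param resp_freq_jitter relative SD of the slowly varying breathing
#'   frequency (default 0.08).
#' @param baseline_amp normal breathing amplitude, arbitrary thermistor
#'   units (default 1).
#' @param amp_mod_sd relative SD of the slow breath-amplitude modulation
#'   (default 0.1).
#' @param drift_amp amplitude of the 0.005-Hz baseline drift, below the
#'   high-pass band (default 0.5).
#' @param noise_sd additive flow noise SD (default 0.05).
#' @param apnea_residual_frac residual flow amplitude during apneas, at
#'   most 0.1 (a >90% drop; default 0.05).
#' @param hypopnea_residual_range residual-amplitude range for hypopneas,
#'   inside `[0.1, 0.7]` (30-90% drop; default `c(0.3, 0.6)`).
#' @param event_duration_range_s event duration range, minimum 10 (default
#'   `c(12, 28)`).
#' @param min_separation_s minimum gap between consecutive events (default
#'   15, so well-separated events never trigger gap merging).
#' @param desat_depth_range_pct desaturation depth range in percent,
#'   minimum 3 (default `c(3, 10)`).
#' @param desat_lag_s lag from event onset to desaturation onset (default
#'   23; must be in (0, 30)).
#' @param spo2_baseline_pct resting saturation (default 97).
#' @param spo2_noise_sd saturation noise SD before quantization (default
#'   0.2).
#' @param spo2_quantize quantize SpO2 to integer percent like a pulse
#'   oximeter (default TRUE).
#' @param artifact_rate fraction of samples replaced by sub-50% dropout
#'   artifacts, injected in 1-3 s bursts (default 0.02).
#' @param seed integer seed; generation is fully reproducible.
#' @return classed list (`"SynthConfig"`).
#' @export
synthConfig <- function(duration_s = 3600, target_ahi = 15,
                        apnea_fraction = 0.5, resp_freq_hz = 0.25,
                        resp_freq_jitter = 0.08, baseline_amp = 1,
                        amp_mod_sd = 0.1, drift_amp = 0.5, noise_sd = 0.05,
                        apnea_residual_frac = 0.05,
                        hypopnea_residual_range = c(0.3, 0.6),
                        event_duration_range_s = c(12, 28),
                        min_separation_s = 15,
                        desat_depth_range_pct = c(3, 10),
                        desat_lag_s = 23, spo2_baseline_pct = 97,
                        spo2_noise_sd = 0.2, spo2_quantize = TRUE,
                        artifact_rate = 0.02, seed = 1L) {
  if (event_duration_range_s[1] < 10)
    stop("event durations must be at least 10 s")
  if (!(desat_lag_s > 0 && desat_lag_s < 30))
    stop("desat_lag_s must satisfy 0 < lag < 30")
  if (desat_depth_range_pct[1] < 3)
    stop("desaturation depth must be at least 3%")
  if (apnea_residual_frac > 0.1)
    stop("apnea residual must be at most 0.1 (>90% drop)")
  if (hypopnea_residual_range[1] < apnea_residual_frac)
    stop("hypopnea residuals must exceed the apnea residual")
  if (hypopnea_residual_range[1] < 0.1 || hypopnea_residual_range[2] > 0.7)
    stop("hypopnea residuals must lie in [0.1, 0.7]")
  structure(as.list(environment()), class = "SynthConfig")
}

#' Generate one annotated synthetic recording
#'
#' Nasal flow is a frequency- and amplitude-modulated sinusoid with slow
#' baseline drift and additive noise; events are scheduled by a renewal
#' process (exponential gaps plus a minimum separation) targeting
#' `target_ahi`, each scaling the flow envelope down to its residual
#' fraction with 1-s raised-cosine edges. SpO2 desaturates by a sampled
#' depth starting `desat_lag_s` after each event onset (half-cosine fall
#' over ~10 s, exponential recovery), is noise-corrupted and
#' integer-quantized, and receives sub-50% dropout bursts at
#' `artifact_rate`. Annotations record every scheduled event exactly.
#'
#' The clean (noise-free, artifact-free) channels and the event schedule
#' are kept in the recording's metadata for verification.
#'
#' @param cfg a [synthConfig()].
#' @param subjectID subject identifier.
#' @return A [Recording-class] with ground-truth annotations.
#' @export
generateRecording <- function(cfg = synthConfig(), subjectID = "synthetic") {
  stopifnot(inherits(cfg, "SynthConfig"))
  restore <- localSeed(cfg$seed)
  on.exit(restore(), add = TRUE)

  fs <- 8
  n <- as.integer(round(cfg$duration_s * fs))
  t <- (seq_len(n) - 1) / fs

  ev <- scheduleEvents(cfg)

  # flow: phase-integrated jittered frequency, slow amplitude modulation
  freq <- cfg$resp_freq_hz * (1 + cfg$resp_freq_jitter * slowNoise(n, fs, 0.02))
  phase <- 2 * pi * cumsum(freq) / fs
  amp <- cfg$baseline_amp * pmax(0.2, 1 + cfg$amp_mod_sd * slowNoise(n, fs, 0.01))
  env <- rep(1, n)
  if (nrow(ev)) {
    for (i in seq_len(nrow(ev))) {
      env <- env * eventEnvelope(t, ev$onset_s[i], ev$onset_s[i] + ev$duration_s[i],
                                 ev$residual[i])
    }
  }
  drift <- cfg$drift_amp * sin(2 * pi * 0.005 * t + stats::runif(1, 0, 2 * pi))
  clean_nf <- amp * env * sin(phase)
  nf <- clean_nf + drift + stats::rnorm(n, sd = cfg$noise_sd)

  # SpO2: baseline with lagged desaturation responses
  sp <- rep(cfg$spo2_baseline_pct, n)
  if (nrow(ev)) {
    for (i in seq_len(nrow(ev))) {
      on <- ev$onset_s[i] + cfg$desat_lag_s
      sp <- sp - ev$desat[i] * desatProfile(t, on, ev$duration_s[i])
    }
  }
  clean_sp <- sp
  sp <- sp + stats::rnorm(n, sd = cfg$spo2_noise_sd)
  if (cfg$spo2_quantize) sp <- round(sp)

  # dropout artifacts in 1-3 s bursts
  if (cfg$artifact_rate > 0) {
    target <- cfg$artifact_rate * n
    dropped <- 0
    guard <- 0
    while (dropped < target && guard < 10000) {
      guard <- guard + 1
      len <- as.integer(round(stats::runif(1, 1, 3) * fs))
      at <- sample.int(n - len, 1)
      sp[at:(at + len - 1)] <- stats::runif(len, 20, 45)
      dropped <- dropped + len
    }
  }

  ann <- data.frame(onset_s = ev$onset_s, duration_s = ev$duration_s,
                    label = ev$label, stringsAsFactors = FALSE)
  Recording(nf = nf, spo2 = sp, sampleRate = fs, subjectID = subjectID,
            annotations = ann,
            metadata = list(config = cfg, clean_nf = clean_nf,
                            clean_spo2 = clean_sp, schedule = ev,
                            realized_ahi = nrow(ev) / (cfg$duration_s / 3600)))
}

# renewal schedule: exponential gaps + minimum separation, events within
# [lead, duration - tail)
scheduleEvents <- function(cfg) {
  mean_dur <- mean(cfg$event_duration_range_s)
  mean_cycle <- 3600 / cfg$target_ahi
  empty <- data.frame(onset_s = numeric(), duration_s = numeric(),
                      label = character(), residual = numeric(),
                      desat = numeric())
  if (cfg$target_ahi <= 0) return(empty)
  exp_mean <- mean_cycle - cfg$min_separation_s - mean_dur
  if (exp_mean <= 0)
    stop("target_ahi of ", cfg$target_ahi,
         " events/h is infeasible with these durations and separation")
  lead <- 40  # breathing history before the first possible event
  t <- lead + cfg$min_separation_s + stats::rexp(1, 1 / exp_mean)
  onset <- dur <- resid <- desat <- numeric(0)
  lab <- character(0)
  tail_guard <- cfg$desat_lag_s + 10
  repeat {
    d <- stats::runif(1, cfg$event_duration_range_s[1], cfg$event_duration_range_s[2])
    if (t + d > cfg$duration_s - tail_guard) break
    apnea <- stats::runif(1) < cfg$apnea_fraction
    onset <- c(onset, t); dur <- c(dur, d)
    lab <- c(lab, if (apnea) "APNEA" else "HYPOPNEA")
    resid <- c(resid,
               if (apnea) stats::runif(1, 0, cfg$apnea_residual_frac)
               else stats::runif(1, cfg$hypopnea_residual_range[1],
                                 cfg$hypopnea_residual_range[2]))
    desat <- c(desat, stats::runif(1, cfg$desat_depth_range_pct[1],
                                   cfg$desat_depth_range_pct[2]))
    t <- t + d + cfg$min_separation_s + stats::rexp(1, 1 / exp_mean)
  }
  data.frame(onset_s = onset, duration_s = dur, label = lab,
             residual = resid, desat = desat, stringsAsFactors = FALSE)
}

# multiplicative flow envelope: residual inside [on, off), raised-cosine
# edges of 1 s
eventEnvelope <- function(t, on, off, residual, edge = 1) {
  e <- rep(1, length(t))
  core <- t >= on & t < off
  e[core] <- residual
  rise <- t >= on - edge & t < on
  e[rise] <- residual + (1 - residual) * 0.5 *
    (1 + cos(pi * (t[rise] - (on - edge)) / edge))
  fall <- t >= off & t < off + edge
  e[fall] <- residual + (1 - residual) * 0.5 *
    (1 - cos(pi * (t[fall] - off) / edge))
  e
}

# unit desaturation profile: half-cosine fall over `fall` s, plateau for
# the event duration, exponential recovery
desatProfile <- function(t, on, event_dur, fall = 10, rec_tau = 12) {
  p <- numeric(length(t))
  fallIdx <- t >= on & t < on + fall
  p[fallIdx] <- 0.5 * (1 - cos(pi * (t[fallIdx] - on) / fall))
  hold_end <- on + max(fall, event_dur)
  holdIdx <- t >= on + fall & t < hold_end
  p[holdIdx] <- 1
  recIdx <- t >= hold_end
  p[recIdx] <- exp(-(t[recIdx] - hold_end) / rec_tau)
  p
}

# low-pass random modulation: interpolated Gaussian knots at `knot_hz`
slowNoise <- function(n, fs, knot_hz) {
  nk <- max(3, ceiling(n / fs * knot_hz) + 2)
  knots <- stats::rnorm(nk)
  stats::approx(seq(0, n - 1, length.out = nk), knots, xout = 0:(n - 1))$y
}

#' Generate a severity-mixed cohort
#'
#' Per-subject target AHIs are drawn from severity-specific ranges (NON
#' U(1, 4.5), MILD U(6, 14), MODERATE U(16, 29), SEVERE U(31, 55), centred
#' near typical group means), and per-subject seeds are derived
#' deterministically from the master seed.
#'
#' @param severity_mix integer vector of length 4: subjects per severity
#'   class (NON, MILD, MODERATE, SEVERE); the reference cohort structure is
#'   `c(2, 12, 5, 5)`.
#' @param seed master seed.
#' @param cfg template [synthConfig()]; `target_ahi` and `seed` are
#'   overridden per subject.
#' @return named list of [Recording-class] objects.
#' @export
generateCohort <- function(severity_mix = c(2, 12, 5, 5), seed = 1L,
                           cfg = synthConfig()) {
  if (length(severity_mix) != 4 || sum(severity_mix) < 1)
    stop("severity_mix must give counts for NON/MILD/MODERATE/SEVERE")
  ranges <- list(c(1, 4.5), c(6, 14), c(16, 29), c(31, 55))
  restore <- localSeed(seed)
  targets <- unlist(lapply(1:4, function(g)
    stats::runif(severity_mix[g], ranges[[g]][1], ranges[[g]][2])))
  restore()
  out <- list()
  for (i in seq_along(targets)) {
    ci <- cfg
    ci$target_ahi <- targets[i]
    ci$seed <- as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483647)
    sid <- sprintf("synth%02d", i)
    out[[sid]] <- generateRecording(ci, subjectID = sid)
  }
  out
}

#' Oracle label sequence from ground-truth annotations
#'
#' The label sequence that [segmentize()] + [labelSegments()] produce from
#' a recording's own annotations — the classifier-free reference used to
#' test the event detector in isolation.
#'
#' @param rec an annotated [Recording-class].
#' @param window_s segment window (default 10).
#' @param cfg a [preprocessConfig()].
#' @return A [LabelSequence-class] (all segments treated as usable).
#' @export
oracleLabelSequence <- function(rec, window_s = 10, cfg = preprocessConfig()) {
  seg <- segmentize(rec, window_s, cfg)
  seg$usable <- TRUE
  seg <- labelSegments(seg, annotations(rec), cfg)
  LabelSequence(seg$label, startOffset = 0L, windowS = window_s,
                subjectID = subjectID(rec))
}
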