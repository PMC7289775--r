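# The reference synthetic cohort (24 subjects, 2/12/5/5 severity mix,
# 1-h recordings, master seed 42), featurized once and shared across the
# acceptance checks.

.cohortCache <- new.env(parent = emptyenv())

studyCohort <- function() {
  if (!exists("recordings", envir = .cohortCache)) {
    assign("recordings",
           generateCohort(c(2, 12, 5, 5), seed = 42,
                          cfg = synthConfig(duration_s = 3600)),
           envir = .cohortCache)
  }
  get("recordings", envir = .cohortCache)
}

studyFeatures <- function() {
  if (!exists("features", envir = .cohortCache)) {
    assign("features", cohortFeatures(studyCohort()), envir = .cohortCache)
  }
  get("features", envir = .cohortCache)
}

studyCV <- function() {
  if (!exists("cv", envir = .cohortCache)) {
    assign("cv", crossvalidate(studyFeatures(), seed = 42, split = "segment"),
           envir = .cohortCache)
  }
  get("cv", envir = .cohortCache)
}
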