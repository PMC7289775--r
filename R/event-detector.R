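# Run-length correction of the predicted 10-s label sequence into discrete
# AH events, AHI estimation and severity grading.

#' Correct a predicted label sequence
#'
#' Two run-length rules, applied in order: (1) an AH event lasts at least
#' 10 s, so under 10-s windows stepped by 1 s a valid event yields at least
#' `min_run` (default 10) consecutive AH starts — shorter AH runs are reset
#' to N; (2) two valid events must be separated by more than `max_gap`
#' (default 5) N starts — shorter N gaps between surviving runs are reset to
#' AH, merging the runs. Merged runs are not re-tested against rule 1.
#' `UNKNOWN` entries count as N for run accounting and come out as N.
#'
#' The correction is idempotent: merged runs are at least `min_run` long and
#' surviving gaps exceed `max_gap`.
#'
#' @param seq a [LabelSequence-class] over consecutive start seconds.
#' @param min_run minimum AH run length (default 10).
#' @param max_gap largest N gap that still merges two valid runs (default
#'   5; a gap of exactly `max_gap` is merged).
#' @return The corrected [LabelSequence-class] over `{"AH","N"}`.
#' @export
correctSequence <- function(seq, min_run = 10L, max_gap = 5L) {
  x <- ifelse(seqLabels(seq) == "AH", "AH", "N")
  if (length(x)) {
    r <- rle(x)
    # rule 1: short AH runs -> N
    r$values[r$values == "AH" & r$lengths < min_run] <- "N"
    r <- rle(inverse.rle(r))
    # rule 2: short N gaps strictly between two valid AH runs -> AH
    if (length(r$values) >= 3) {
      inner <- 2:(length(r$values) - 1)
      fill <- inner[r$values[inner] == "N" & r$lengths[inner] <= max_gap &
                    r$values[inner - 1] == "AH" & r$values[inner + 1] == "AH"]
      r$values[fill] <- "AH"
    }
    x <- inverse.rle(r)
  }
  LabelSequence(x, startOffset = seq@startOffset, windowS = seq@windowS,
                subjectID = seq@subjectID)
}

#' Derive event intervals from a corrected sequence
#'
#' Each maximal AH run over start seconds `[a, b]` becomes the event
#' `[a, b + window)` seconds (every 10-s segment covers `[t, t + 10)`).
#' Events come out sorted and non-overlapping.
#'
#' @param seq a corrected [LabelSequence-class].
#' @return data.frame with columns `start_s`, `end_s`, `duration_s`.
#' @export
eventsFromSequence <- function(seq) {
  x <- seqLabels(seq)
  w <- seq@windowS
  if (length(x) == 0 || !any(x == "AH"))
    return(data.frame(start_s = numeric(), end_s = numeric(),
                      duration_s = numeric()))
  r <- rle(x)
  ends <- cumsum(r$lengths)
  begs <- ends - r$lengths + 1
  ah <- which(r$values == "AH")
  start <- seq@startOffset + begs[ah] - 1
  end <- seq@startOffset + ends[ah] - 1 + w
  data.frame(start_s = start, end_s = end, duration_s = end - start)
}

#' Apnea-hypopnea index
#'
#' @param events data.frame of detected events (or anything with one row
#'   per event).
#' @param analyzed_duration_s the analysed recording duration in seconds.
#' @return events per hour.
#' @export
computeAHI <- function(events, analyzed_duration_s) {
  if (!is.numeric(analyzed_duration_s) || analyzed_duration_s <= 0)
    stop("analyzed_duration_s must be positive")
  nrow(events) / (analyzed_duration_s / 3600)
}

#' Severity grade of an AHI
#'
#' Standard cutoffs 5, 15 and 30 events/h: `NON` below 5, `MILD` in
#' `[5, 15)`, `MODERATE` in `[15, 30)`, `SEVERE` at or above 30.
#'
#' @param ahi events per hour (vectorised).
#' @return factor with levels `NON`, `MILD`, `MODERATE`, `SEVERE`.
#' @export
severityOf <- function(ahi) {
  if (any(ahi < 0)) stop("ahi must be nonnegative")
  cut(ahi, breaks = c(-Inf, 5, 15, 30, Inf), right = FALSE,
      labels = c("NON", "MILD", "MODERATE", "SEVERE"))
}

#' Severity levels
#' @return character vector of the four severity classes in order.
#' @export
severityLevels <- function() c("NON", "MILD", "MODERATE", "SEVERE")
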