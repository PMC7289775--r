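# Evaluation metrics: 2x2 segment confusion metrics, 4x4 severity
# classification report (per-cutoff SEN/SPE/PPV/ACC, their means, Cohen's
# kappa), and AHI agreement (Pearson + Bland-Altman).

#' Round half up
#'
#' Displayed metrics use half-up rounding at a fixed number of decimals
#' (base `round()` rounds half to even).
#'
#' @param x numeric.
#' @param digits decimals to keep.
#' @return numeric.
#' @export
roundHalfUp <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Segment-level confusion metrics
#'
#' AH is the positive class. Accuracy `(tp+tn)/total`, sensitivity
#' `tp/(tp+fn)`, specificity `tn/(tn+fp)`, as percentages rounded half-up
#' to `digits` decimals.
#'
#' @param c list or named vector with `tp`, `fp`, `fn`, `tn`.
#' @param digits decimals for the returned percentages (default 1;
#'   `digits = NULL` returns full precision).
#' @return named list with `acc`, `sen`, `spe` (percent).
#' @export
segmentMetrics <- function(c, digits = 1) {
  c <- as.list(c)
  tp <- c$tp; fp <- c$fp; fn <- c$fn; tn <- c$tn
  total <- tp + fp + fn + tn
  if (total <= 0) stop("empty confusion matrix")
  if (tp + fn == 0) stop("sensitivity undefined: no positive reference segments")
  if (tn + fp == 0) stop("specificity undefined: no negative reference segments")
  out <- list(acc = 100 * (tp + tn) / total,
              sen = 100 * tp / (tp + fn),
              spe = 100 * tn / (tn + fp))
  if (!is.null(digits)) out <- lapply(out, roundHalfUp, digits = digits)
  out
}

#' Build a severity confusion matrix
#'
#' Rows are the estimated class, columns the reference class, both ordered
#' `NON`, `MILD`, `MODERATE`, `SEVERE`.
#'
#' @param est,ref severity classes (factors or characters).
#' @return 4x4 integer matrix.
#' @export
severityMatrix <- function(est, ref) {
  lv <- severityLevels()
  m <- table(factor(as.character(est), levels = lv),
             factor(as.character(ref), levels = lv))
  matrix(as.integer(m), 4, 4, dimnames = list(estimated = lv, reference = lv))
}

#' Pool a severity matrix at one AHI cutoff
#'
#' Classes at or above the cutoff's first severity (5 -> MILD+, 15 ->
#' MODERATE+, 30 -> SEVERE) are positive.
#'
#' @param m 4x4 severity matrix (estimated rows, reference columns).
#' @param cutoff 5, 15 or 30 events/h.
#' @return list with `tp`, `fp`, `fn`, `tn`.
#' @export
binarizeSeverity <- function(m, cutoff) {
  first <- switch(as.character(cutoff), "5" = 2L, "15" = 3L, "30" = 4L,
                  stop("cutoff must be 5, 15 or 30"))
  pos <- first:4; neg <- seq_len(first - 1)
  list(tp = sum(m[pos, pos]), fp = sum(m[pos, neg]),
       fn = sum(m[neg, pos]), tn = sum(m[neg, neg]))
}

#' Unweighted Cohen's kappa of a square confusion matrix
#'
#' @param m square count matrix (rows estimated, columns reference).
#' @return kappa in `[-1, 1]`.
#' @export
cohensKappa <- function(m) {
  n <- sum(m)
  if (n <= 0) stop("empty matrix")
  po <- sum(diag(m)) / n
  pe <- sum(rowSums(m) * colSums(m)) / n^2
  if (pe >= 1) return(1)
  (po - pe) / (1 - pe)
}

#' Severity classification report
#'
#' Per-cutoff (5/15/30 events/h) sensitivity, specificity, positive
#' predictive value and accuracy, their cross-cutoff means, and unweighted
#' Cohen's kappa on the full 4x4 matrix. Percentages are rounded half-up to
#' one decimal and the means are taken over the rounded per-cutoff values
#' (the convention of the reported tables); kappa is rounded to two
#' decimals.
#'
#' @param m 4x4 severity matrix (estimated rows, reference columns).
#' @return list with `per_cutoff` (data.frame: cutoff, sen, spe, ppv, acc),
#'   `means` (named numeric) and `kappa`.
#' @export
severityReport <- function(m) {
  if (sum(m) <= 0) stop("empty severity matrix")
  rows <- lapply(c(5, 15, 30), function(co) {
    b <- binarizeSeverity(m, co)
    total <- b$tp + b$fp + b$fn + b$tn
    data.frame(cutoff = co,
               sen = roundHalfUp(100 * b$tp / (b$tp + b$fn)),
               spe = roundHalfUp(100 * b$tn / (b$tn + b$fp)),
               ppv = roundHalfUp(100 * b$tp / (b$tp + b$fp)),
               acc = roundHalfUp(100 * (b$tp + b$tn) / total))
  })
  per <- do.call(rbind, rows)
  means <- vapply(c("sen", "spe", "ppv", "acc"),
                  function(k) roundHalfUp(mean(per[[k]])), numeric(1))
  list(per_cutoff = per, means = means,
       kappa = roundHalfUp(cohensKappa(m), 2))
}

#' AHI agreement between estimate and reference
#'
#' Pearson correlation plus Bland-Altman mean difference and 95% limits of
#' agreement (mean difference +/- 1.96 SD of the differences,
#' estimate minus reference).
#'
#' @param est,ref numeric AHI vectors (same length, >= 3 pairs).
#' @return list with `pearson_r`, `mean_diff`, `loa_low`, `loa_high`, `n`.
#' @export
ahiAgreement <- function(est, ref) {
  if (length(est) != length(ref) || length(est) < 3)
    stop("need at least 3 paired AHI values")
  if (stats::sd(est) == 0 || stats::sd(ref) == 0)
    stop("correlation undefined: constant AHI column")
  d <- est - ref
  list(pearson_r = stats::cor(est, ref),
       mean_diff = mean(d),
       loa_low = mean(d) - 1.96 * stats::sd(d),
       loa_high = mean(d) + 1.96 * stats::sd(d),
       n = length(d))
}
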