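# The cascaded segment classifier: a 10-tree random forest over 60-s
# segments screens the night, and a 20-tree forest over 10-s segments
# classifies only the screened-in starts. Class weights are the inverse
# ratio of the class counts, offsetting the heavy AH/N imbalance.

#' Train the cascaded detector
#'
#' Fits the 60-s screening forest (10 CARTs, reduced feature set `Fha`,
#' `Fhap`, `Spstd`, `Spran`, `Spdum`, `Spdua`) and the 10-s forest (20
#' CARTs, all 19 features) on reference-labelled feature tables. Both
#' stages are trained independently on the reference labels. Class weights
#' are proportional to the inverse of the class counts.
#'
#' @param feat60 feature table of 60-s training segments
#'   ([SegmentFeatures-class] or [featureFrame()] data.frame with a `label`
#'   column).
#' @param feat10 feature table of 10-s training segments.
#' @param seed integer seed; training is reproducible given the seed.
#' @param gating `"contain"` (default: a 10-s window must be fully inside an
#'   AH-screened 60-s window) or `"overlap"` (any overlap screens in).
#' @param num_trees_60,num_trees_10 forest sizes (defaults 10 and 20).
#' @return A [CascadeModel-class].
#' @export
trainCascade <- function(feat60, feat10, seed = 1L,
                         gating = c("contain", "overlap"),
                         num_trees_60 = 10L, num_trees_10 = 20L) {
  gating <- match.arg(gating)
  df60 <- asFeatureDF(feat60)
  df10 <- asFeatureDF(feat10)
  f60 <- fitForest(df60, screenFeatureNames(), num_trees_60, seed)
  f10 <- fitForest(df10, featureNames(), num_trees_10, seed + 1L)
  new("CascadeModel",
      detector60 = f60$fit, detector10 = f10$fit,
      features60 = screenFeatureNames(), features10 = featureNames(),
      classWeights60 = f60$weights, classWeights10 = f10$weights,
      gating = gating, seed = as.integer(seed),
      trainInfo = list(num_trees_60 = as.integer(num_trees_60),
                       num_trees_10 = as.integer(num_trees_10),
                       n_train_60 = nrow(df60), n_train_10 = nrow(df10),
                       mtry = "ranger default (floor(sqrt(p)))",
                       min_node_size = "ranger default (1)"))
}

fitForest <- function(df, feats, num_trees, seed) {
  miss <- setdiff(feats, names(df))
  if (length(miss))
    stop("feature table missing columns: ", paste(miss, collapse = ", "))
  if (!"label" %in% names(df)) stop("feature table has no label column")
  y <- factor(df$label, levels = c("N", "AH"))
  if (any(is.na(y))) stop("labels must be 'AH' or 'N'")
  cnt <- table(y)
  if (any(cnt == 0))
    stop("training labels contain a single class; both AH and N are required")
  w <- as.numeric(sum(cnt) / cnt)   # inverse ratio of class counts
  names(w) <- names(cnt)
  dat <- df[feats]
  dat$.label <- y
  # probability forest + fixed 0.5 threshold: per-segment predictions are
  # deterministic and independent of which other rows share the predict
  # call (majority voting breaks split-vote ties at random)
  fit <- ranger::ranger(
    dependent.variable.name = ".label", data = dat,
    num.trees = num_trees, probability = TRUE,
    class.weights = w, seed = seed, num.threads = 1L
  )
  list(fit = fit, weights = w)
}

forestClass <- function(fit, df) {
  p <- stats::predict(fit, data = df, num.threads = 1L)$predictions
  ifelse(p[, "AH"] > 0.5, "AH", "N")
}

asFeatureDF <- function(x) {
  if (is(x, "SegmentFeatures")) featureFrame(x)
  else if (is.data.frame(x)) x
  else stop("expected a SegmentFeatures or a feature data.frame")
}

#' Predict 60-s segment classes
#'
#' @param model a [CascadeModel-class].
#' @param feat60 feature table of 60-s segments.
#' @return data.frame with `start_s` and predicted `class` (`"AH"`/`"N"`)
#'   per usable segment.
#' @export
predict60 <- function(model, feat60) {
  df <- asFeatureDF(feat60)
  miss <- setdiff(model@features60, names(df))
  if (length(miss))
    stop("feature table missing columns: ", paste(miss, collapse = ", "))
  data.frame(start_s = df$start_s,
             class = forestClass(model@detector60, df[model@features60]))
}

#' Predict 10-s segment classes directly (no gating)
#'
#' @param model a [CascadeModel-class].
#' @param feat10 feature table of 10-s segments.
#' @return data.frame with `start_s` and predicted `class`.
#' @export
predict10 <- function(model, feat10) {
  df <- asFeatureDF(feat10)
  miss <- setdiff(model@features10, names(df))
  if (length(miss))
    stop("feature table missing columns: ", paste(miss, collapse = ", "))
  data.frame(start_s = df$start_s,
             class = forestClass(model@detector10, df[model@features10]))
}

#' Run the full cascade on one recording
#'
#' A 10-s start second is sent to the 10-s forest only when screened in by
#' the gating rule (`"contain"`: some AH-predicted 60-s segment fully
#' contains the 10-s window; `"overlap"`: any overlap counts); otherwise it
#' is labelled `"N"`. Unusable 10-s segments are `"UNKNOWN"`. The output
#' covers every start second from 0 to `duration - 10`.
#'
#' @param model a [CascadeModel-class].
#' @param feat60 feature table of the recording's 60-s segments.
#' @param feat10 feature table of the recording's 10-s segments.
#' @param duration_s recording duration in seconds (defaults to the largest
#'   10-s start + 10).
#' @param restrict_starts optional integer vector: only these 10-s start
#'   seconds are classified (others become `"UNKNOWN"`); used by the
#'   cross-validation harness.
#' @return A [LabelSequence-class].
#' @export
predictCascade <- function(model, feat60, feat10, duration_s = NULL,
                           restrict_starts = NULL) {
  df60 <- asFeatureDF(feat60)
  df10 <- asFeatureDF(feat10)
  sid <- unique(c(df60$subject_id, df10$subject_id))
  sid <- sid[!is.na(sid)]
  if (length(sid) > 1)
    stop("feature tables mix recordings: ", paste(sid, collapse = ", "))
  if (length(sid) == 0) sid <- "anonymous"
  if (is.null(duration_s)) duration_s <- max(df10$start_s) + 10
  starts <- 0:(as.integer(duration_s) - 10L)
  labels <- rep("UNKNOWN", length(starts))

  p60 <- predict60(model, df60)
  ah60 <- p60$start_s[p60$class == "AH"]
  gateOpen <- logical(length(starts))
  if (length(ah60)) {
    lo <- if (model@gating == "contain") ah60 else ah60 - 9L
    hi <- if (model@gating == "contain") ah60 + 50L else ah60 + 59L
    iv <- mergeIntervals(lo, hi + 1L)  # half-open on the integer grid
    for (r in seq_len(nrow(iv)))
      gateOpen[starts >= iv[r, 1] & starts < iv[r, 2]] <- TRUE
  }

  usable <- starts %in% df10$start_s
  labels[usable & !gateOpen] <- "N"
  todo <- usable & gateOpen
  if (any(todo)) {
    sel <- df10[match(starts[todo], df10$start_s), ]
    labels[todo] <- forestClass(model@detector10, sel[model@features10])
  }
  if (!is.null(restrict_starts))
    labels[!(starts %in% restrict_starts)] <- "UNKNOWN"
  LabelSequence(labels, startOffset = 0L, windowS = 10, subjectID = sid)
}

#' Twofold cross-validation over a cohort
#'
#' Splits the pooled segments (default `"segment"` mode) or the
#' recordings (`"subject"` mode) into two folds; each fold's model is
#' trained on the other fold and predicts its own segments, so every
#' segment is predicted exactly once while unseen in training. Per
#' recording, the two folds' predictions are combined into one full label
#' sequence.
#'
#' Note that segment-level splitting lets overlapping windows of the same
#' event appear in both folds, which flatters the segment metrics; the
#' subject-level mode avoids that leakage.
#'
#' @param cohort list of per-recording entries, each a list with elements
#'   `feat60`, `feat10` ([SegmentFeatures-class]) and `duration_s`; the
#'   output of [cohortFeatures()].
#' @param seed integer seed for the fold split and training.
#' @param split `"segment"` (default) or `"subject"`.
#' @param gating gating rule passed to [trainCascade()].
#' @return list with `sequences` (named list of [LabelSequence-class], one
#'   per recording), `confusion` (pooled tp/fp/fn/tn over predicted usable
#'   10-s segments), `fold` (the fold assignments) and `models`.
#' @export
crossvalidate <- function(cohort, seed = 1L, split = c("segment", "subject"),
                          gating = c("contain", "overlap")) {
  split <- match.arg(split)
  gating <- match.arg(gating)
  if (length(cohort) < 1) stop("empty cohort")
  df60 <- do.call(rbind, lapply(cohort, function(e) asFeatureDF(e$feat60)))
  df10 <- do.call(rbind, lapply(cohort, function(e) asFeatureDF(e$feat10)))
  if (nrow(df10) < 2) stop("fewer segments than folds")

  rng <- localSeed(seed)
  on.exit(rng(), add = TRUE)
  if (split == "subject") {
    subj <- vapply(cohort, function(e) unique(asFeatureDF(e$feat10)$subject_id),
                   character(1))
    if (length(subj) < 2) stop("subject-level split needs >= 2 recordings")
    half <- sample(seq_along(subj), floor(length(subj) / 2))
    fold60 <- ifelse(df60$subject_id %in% subj[half], 1L, 2L)
    fold10 <- ifelse(df10$subject_id %in% subj[half], 1L, 2L)
  } else {
    fold60 <- sample(rep_len(1:2, nrow(df60)))
    fold10 <- sample(rep_len(1:2, nrow(df10)))
  }

  models <- list()
  seqs <- stats::setNames(vector("list", length(cohort)),
                          vapply(cohort, function(e)
                            unique(asFeatureDF(e$feat10)$subject_id),
                            character(1)))
  for (f in 1:2) {
    models[[f]] <- trainCascade(df60[fold60 != f, ], df10[fold10 != f, ],
                                seed = seed + f, gating = gating)
  }
  for (j in seq_along(cohort)) {
    e <- cohort[[j]]
    e60 <- asFeatureDF(e$feat60)
    e10 <- asFeatureDF(e$feat10)
    sid <- unique(e10$subject_id)
    lab <- NULL
    for (f in 1:2) {
      inFold <- fold10[df10$subject_id == sid] == f
      starts <- e10$start_s[inFold]
      if (length(starts) == 0) next
      sq <- predictCascade(models[[f]], e60, e10, duration_s = e$duration_s,
                           restrict_starts = starts)
      if (is.null(lab)) lab <- seqLabels(sq)
      else {
        upd <- seqLabels(sq) != "UNKNOWN"
        lab[upd] <- seqLabels(sq)[upd]
      }
    }
    seqs[[sid]] <- LabelSequence(lab, startOffset = 0L, windowS = 10,
                                 subjectID = sid)
  }

  conf <- pooledConfusion(seqs, cohort)
  list(sequences = seqs, confusion = conf,
       fold = list(fold60 = fold60, fold10 = fold10, split = split),
       models = models)
}

pooledConfusion <- function(seqs, cohort) {
  tp <- fp <- fn <- tn <- 0L
  for (e in cohort) {
    e10 <- asFeatureDF(e$feat10)
    sid <- unique(e10$subject_id)
    sq <- seqs[[sid]]
    pred <- seqLabels(sq)[match(e10$start_s, seqStarts(sq))]
    ok <- pred %in% c("AH", "N")
    ref <- e10$label[ok]; pred <- pred[ok]
    tp <- tp + sum(pred == "AH" & ref == "AH")
    fp <- fp + sum(pred == "AH" & ref == "N")
    fn <- fn + sum(pred == "N" & ref == "AH")
    tn <- tn + sum(pred == "N" & ref == "N")
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

# set the RNG reproducibly and return a restore function
localSeed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
}
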