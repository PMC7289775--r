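# build a labelled feature data.frame with all 19 features; `x` drives the
# class through one chosen feature, the rest stay at baseline noise
syntheticTable <- function(n_ah, n_n, seed = 1, window = 10,
                           subject = "synthA") {
  set.seed(seed)
  n <- n_ah + n_n
  df <- as.data.frame(matrix(abs(rnorm(n * 19, sd = 0.01)), n, 19))
  names(df) <- featureNames()
  lab <- c(rep("AH", n_ah), rep("N", n_n))
  # well-separated classes: apneic segments have high Fapp/Fhap and deep
  # desaturation; normal ones do not
  df$Fapp <- ifelse(lab == "AH", 0.9, 0.05) + rnorm(n, sd = 0.03)
  df$Fhap <- pmin(1, df$Fapp + 0.05)
  df$Fha <- df$Fhap * 4
  df$Spldm <- ifelse(lab == "AH", 5, 0.2) + rnorm(n, sd = 0.2)
  df$Spstd <- ifelse(lab == "AH", 1.5, 0.2) + abs(rnorm(n, sd = 0.1))
  df$Spran <- df$Spstd * 3
  df$Spdum <- ifelse(lab == "AH", 8, 0.5) + rnorm(n, sd = 0.3)
  df$Spdua <- df$Spdum * 0.8
  df$start_s <- seq_len(n) - 1L
  df$window_s <- window
  df$label <- lab
  df$usable <- TRUE
  df$subject_id <- subject
  df
}

test_that("class weights are the inverse ratio of the class counts", {
  tr60 <- syntheticTable(20, 180, window = 60)
  tr10 <- syntheticTable(20, 180)
  m <- trainCascade(tr60, tr10, seed = 7)
  w <- m@classWeights10
  expect_equal(w[["AH"]] / w[["N"]], 9)  # 10% AH / 90% N
  expect_error(trainCascade(syntheticTable(0, 50, window = 60),
                            tr10, seed = 1), "single class")
})

test_that("training and prediction are deterministic given the seed", {
  tr60 <- syntheticTable(30, 170, seed = 2, window = 60)
  tr10 <- syntheticTable(30, 170, seed = 3)
  te10 <- syntheticTable(25, 75, seed = 4)
  m1 <- trainCascade(tr60, tr10, seed = 11)
  m2 <- trainCascade(tr60, tr10, seed = 11)
  expect_identical(predict10(m1, te10)$class, predict10(m2, te10)$class)
  p <- predict60(m1, syntheticTable(25, 75, seed = 5, window = 60))
  p2 <- predict60(m1, syntheticTable(25, 75, seed = 5, window = 60))
  expect_identical(p$class, p2$class)
})

test_that("well-separated synthetic features are classified almost perfectly", {
  tr60 <- syntheticTable(50, 450, seed = 12, window = 60)
  tr10 <- syntheticTable(50, 450, seed = 13)
  te10 <- syntheticTable(50, 450, seed = 14)
  m <- trainCascade(tr60, tr10, seed = 21)
  acc <- mean(predict10(m, te10)$class == te10$label)
  expect_gt(acc, 0.95)
})

test_that("prediction rejects tables with missing feature columns", {
  tr60 <- syntheticTable(30, 170, window = 60)
  tr10 <- syntheticTable(30, 170)
  m <- trainCascade(tr60, tr10, seed = 1)
  broken <- tr60[, setdiff(names(tr60), "Spdum")]
  expect_error(predict60(m, broken), "Spdum")
})

test_that("a single depth-limited tree reproduces a hand-set threshold rule", {
  # effectively one feature (all columns equal) with an empty margin
  # around x = 0.5: the only candidate split lies inside the margin, so a
  # 1-tree forest must equal the threshold rule outside it
  set.seed(31)
  tr <- syntheticTable(100, 100, seed = 31)
  x <- c(runif(100, 0.7, 1), runif(100, 0, 0.3))
  for (f in featureNames()) tr[[f]] <- x
  tr$label <- ifelse(x > 0.5, "AH", "N")
  m <- trainCascade(transform(tr, window_s = 60), tr, seed = 5,
                    num_trees_60 = 1, num_trees_10 = 1)
  te <- tr
  grid <- seq(0.05, 0.95, by = 0.005)[1:200]
  for (f in featureNames()) te[[f]] <- grid
  p <- predict10(m, te)$class
  away <- grid < 0.3 | grid > 0.7
  expect_identical(p[away], ifelse(grid > 0.5, "AH", "N")[away])
})

test_that("gating closed labels everything N; gating open defers to the 10-s stage", {
  cfg <- synthConfig(duration_s = 400, target_ahi = 18, artifact_rate = 0,
                     seed = 8)
  pr <- prepareRecording(generateRecording(cfg, "gate"))
  tr60 <- featureFrame(pr$feat60)
  tr10 <- featureFrame(pr$feat10)
  m <- trainCascade(tr60, tr10, seed = 3)

  # force the 60-s screen shut / open by overriding its predictions through
  # degenerate feature tables
  allN <- tr60; allN[screenFeatureNames()] <- 0
  shut <- predictCascade(m, allN, tr10, duration_s = pr$duration_s)
  expect_true(all(seqLabels(shut) %in% c("N", "UNKNOWN")))

  raw10 <- predict10(m, tr10)
  allAH <- tr60
  for (f in screenFeatureNames()) allAH[[f]] <- max(tr10[[f]]) + 10
  open <- predictCascade(m, allAH, tr10, duration_s = pr$duration_s)
  openLab <- seqLabels(open)[match(raw10$start_s, seqStarts(open))]
  if (all(predict60(m, allAH)$class == "AH"))
    expect_identical(openLab, raw10$class)

  # monotonicity: cascade AH starts form a subset of the raw 10-s AH starts
  casc <- predictCascade(m, tr60, tr10, duration_s = pr$duration_s)
  cascAH <- seqStarts(casc)[seqLabels(casc) == "AH"]
  rawAH <- raw10$start_s[raw10$class == "AH"]
  expect_true(all(cascAH %in% rawAH))
})

test_that("twofold cross-validation predicts each segment exactly once", {
  recs <- list(
    a = generateRecording(synthConfig(duration_s = 400, target_ahi = 20,
                                      artifact_rate = 0, seed = 41), "a"),
    b = generateRecording(synthConfig(duration_s = 400, target_ahi = 10,
                                      artifact_rate = 0, seed = 42), "b"),
    c = generateRecording(synthConfig(duration_s = 400, target_ahi = 25,
                                      artifact_rate = 0, seed = 43), "c"),
    d = generateRecording(synthConfig(duration_s = 400, target_ahi = 15,
                                      artifact_rate = 0, seed = 44), "d")
  )
  cohort <- cohortFeatures(recs)
  cv <- crossvalidate(cohort, seed = 9)
  # every usable 10-s segment got exactly one prediction
  for (e in cohort) {
    ff <- featureFrame(e$feat10)
    sq <- cv$sequences[[unique(ff$subject_id)]]
    pred <- seqLabels(sq)[match(ff$start_s, seqStarts(sq))]
    expect_true(all(pred %in% c("AH", "N")))
  }
  expect_equal(sum(unlist(cv$confusion)),
               sum(vapply(cohort, function(e) ncol(e$feat10), numeric(1))))
  # same seed -> same folds
  cv2 <- crossvalidate(cohort, seed = 9)
  expect_identical(cv$fold, cv2$fold)

  # subject-level split keeps each subject in one fold
  cvs <- crossvalidate(cohort, seed = 9, split = "subject")
  for (sid in names(recs)) {
    f <- cvs$fold$fold10[do.call(rbind, lapply(cohort, function(e)
      featureFrame(e$feat10)))$subject_id == sid]
    expect_equal(length(unique(f)), 1)
  }
})
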