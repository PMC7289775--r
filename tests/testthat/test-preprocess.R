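test_that("artifact removal masks sub-50% SpO2 without touching values", {
  rec <- Recording(nf = numeric(3), spo2 = c(97, 45, 96), sampleRate = 8)
  out <- suppressMessages(removeArtifacts(rec))
  expect_equal(validMask(out), c(TRUE, FALSE, TRUE))
  expect_equal(oxSat(out), c(97, 45, 96))

  clean <- Recording(nf = numeric(16), spo2 = rep(95, 16), sampleRate = 8)
  expect_equal(invalidFraction(suppressMessages(removeArtifacts(clean))), 0)
})

test_that("generator dropout rate is recovered as the invalid fraction", {
  rec <- generateRecording(synthConfig(duration_s = 1800, target_ahi = 10,
                                       artifact_rate = 0.056, seed = 3))
  out <- suppressMessages(removeArtifacts(rec))
  expect_lt(abs(invalidFraction(out) - 0.056), 0.01)
})

test_that("NF filter rejects DC and drift but passes the breathing band", {
  fs <- 8
  t <- seq(0, 120 - 1 / fs, by = 1 / fs)
  # DC is rejected everywhere (zero-phase pass, padded edges)
  y <- filterNF(rep(3, length(t)), fs)
  expect_lt(max(abs(y)), 0.02)
  # 0.3-Hz sinusoid: amplitude preserved within 5% in the passband
  x <- sin(2 * pi * 0.3 * t)
  y <- filterNF(x, fs)
  mid <- (30 * fs):(90 * fs)
  expect_lt(abs(max(abs(y[mid])) - 1), 0.05)
  # slow 0.005-Hz drift + 0.3-Hz breathing: the drift is stripped; the
  # clean reference carries the causal moving average's 1.5-sample delay
  drift <- 5 * sin(2 * pi * 0.005 * t)
  y <- filterNF(x + drift, fs)
  xdel <- sin(2 * pi * 0.3 * (t - 1.5 / fs))
  expect_gt(stats::cor(y[mid], xdel[mid]), 0.99)
  expect_error(filterNF(numeric(5), fs), "warm-up")
})

test_that("SpO2 alignment advances the channel by tau seconds", {
  n <- 200 * 8
  sp <- rep(97, n)
  sp[(100 * 8 + 1):(102 * 8)] <- 80  # dip at t = 100 s
  rec <- Recording(nf = numeric(n), spo2 = sp, sampleRate = 8)
  out <- alignSpO2(rec, preprocessConfig(tau_s = 23))
  dip <- (which(oxSat(out) < 90)[1] - 1) / 8
  expect_equal(dip, 77)
  # trailing tau seconds invalidated
  expect_true(all(!validMask(out)[(n - 23 * 8 + 1):n]))
  expect_error(preprocessConfig(tau_s = 0), "tau_s")
  expect_error(alignSpO2(Recording(nf = numeric(80), spo2 = rep(97, 80))),
               "shorter")
})

test_that("alignment then inverse shift restores SpO2 where both valid", {
  set.seed(5)
  n <- 120 * 8
  sp <- 97 + cumsum(rnorm(n, sd = 0.05))
  rec <- Recording(nf = numeric(n), spo2 = sp, sampleRate = 8)
  cfg <- preprocessConfig(tau_s = 23)
  fwd <- alignSpO2(rec, cfg)
  sh <- 23 * 8
  restored <- c(rep(NA, sh), oxSat(fwd)[1:(n - sh)])
  ok <- which(!is.na(restored) & validMask(rec)[1:n])
  ok <- ok[ok <= n - sh + sh]  # region valid in both
  expect_equal(restored[ok], sp[ok])
})

test_that("aligned desaturation co-occurs with the flow event", {
  cfg <- synthConfig(duration_s = 900, target_ahi = 20, desat_lag_s = 23,
                     spo2_quantize = FALSE, spo2_noise_sd = 0,
                     artifact_rate = 0, desat_depth_range_pct = c(5, 5),
                     seed = 9)
  rec <- generateRecording(cfg)
  ann <- annotations(rec)
  expect_gt(nrow(ann), 0)
  out <- alignSpO2(rec, preprocessConfig(tau_s = 23))
  gap_ok <- c(TRUE, diff(ann$onset_s) - ann$duration_s[-nrow(ann)] > 90)
  ann <- ann[gap_ok, , drop = FALSE]
  for (i in seq_len(nrow(ann))) {
    seg <- oxSat(out)
    from <- as.integer(ann$onset_s[i] * 8)
    win <- seg[max(1, from - 10 * 8):min(length(seg), from + 15 * 8)]
    t_dip <- (max(1, from - 10 * 8) + which(win < 97 - 0.3)[1] - 2) / 8
    expect_lt(abs(t_dip - ann$onset_s[i]), 2.1)
  }
})

test_that("segmentation counts follow floor(duration) - window + 1", {
  rec <- breathingRecording(duration_s = 120)
  expect_equal(nrow(segmentize(rec, 60)), 61)
  expect_equal(nrow(segmentize(rec, 10)), 111)
  expect_equal(segmentize(rec, 10)$start_s, 0:110)
  short <- breathingRecording(duration_s = 9)
  expect_warning(seg <- segmentize(short, 10), "shorter")
  expect_equal(nrow(seg), 0)
})

test_that("segments overlapping too many invalid samples become unusable", {
  rec <- breathingRecording(duration_s = 60)
  rec@validMask[1:(2 * 8)] <- FALSE  # 2 s invalid at the start
  seg <- segmentize(rec, 10)
  expect_false(seg$usable[1])   # 20% invalid
  expect_true(seg$usable[2])    # 10%, not above the 10% tolerance
  expect_true(all(seg$usable[3:nrow(seg)]))
})

test_that("the >5 s labelling rule is strict and uses the event union", {
  rec <- flatRecording(200)
  seg <- data.frame(start_s = 100L, window_s = 10L, usable = TRUE,
                    label = NA_character_)
  lab <- function(ann) labelSegments(seg, ann)$label
  expect_equal(lab(data.frame(onset_s = 104, duration_s = 26, label = "A")), "AH")
  expect_equal(lab(data.frame(onset_s = 105, duration_s = 25, label = "A")), "N")
  # two sub-events inside the segment: union overlap 8 s
  two <- data.frame(onset_s = c(100, 106), duration_s = c(4, 4),
                    label = c("A", "A"))
  expect_equal(lab(two), "AH")
  expect_equal(bruteOverlap(100, 10, two), 8, tolerance = 0.01)
})

test_that("labelling is invariant to annotation order and event splitting", {
  set.seed(11)
  rec <- flatRecording(300)
  seg <- segmentize(rec, 10)
  for (k in 1:5) {
    on <- sort(runif(3, 20, 250))
    du <- runif(3, 8, 30)
    ann <- data.frame(onset_s = on, duration_s = du, label = "APNEA")
    ref <- labelSegments(seg, ann)$label
    # permuted
    perm <- ann[sample(nrow(ann)), ]
    expect_equal(labelSegments(seg, perm)$label, ref)
    # split each event into two abutting halves
    split <- data.frame(
      onset_s = c(on, on + du / 2), duration_s = c(du / 2, du / 2),
      label = "APNEA")
    expect_equal(labelSegments(seg, split)$label, ref)
    # brute-force union overlap agrees on a sample of segments
    for (s in c(0, 50, 113, 200)) {
      ov <- bruteOverlap(s, 10, ann)
      expect_equal(ref[seg$start_s == s] == "AH", ov > 5 + 1e-9)
    }
  }
})
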