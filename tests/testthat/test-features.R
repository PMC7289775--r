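test_that("breath detection pairs alternating extrema into breaths", {
  fs <- 8
  # one full 0.25-Hz cycle, amplitude a -> one breath with Ft ~ 2a
  a <- 0.8
  t4 <- seq(0, 4 - 1 / fs, by = 1 / fs)
  b <- detectBreaths(a * sin(2 * pi * 0.25 * t4), fs)
  expect_equal(nrow(b), 1)
  expect_equal(b$tidal_volume, 2 * a, tolerance = 0.05)
  # flat signal -> no breaths, not an error
  expect_equal(nrow(detectBreaths(numeric(80), fs)), 0)
  # 10 s of 0.3-Hz breathing -> floor(10 * 0.3) = 3 breaths
  t10 <- seq(0, 10 - 1 / fs, by = 1 / fs)
  expect_equal(nrow(detectBreaths(sin(2 * pi * 0.3 * t10), fs)), 3)
})

test_that("rolling baselines use the 30-s lookback with in-segment fallback", {
  br <- data.frame(t_max_s = c(75, 80, 85), t_min_s = c(77, 82, 87),
                   t_mid_s = c(76, 81, 86), tidal_volume = c(1.0, 0.4, 0.9))
  sp <- rep(97, 8 * 200)
  bl <- rollingBaselines(br, sp, rep(TRUE, length(sp)), 100, 10)
  expect_equal(bl$fb, 1.0)
  expect_equal(bl$spbm, 97)
  expect_equal(bl$spba, 97)
  # constant SpO2 -> Spldm equals Splda downstream
  f <- spo2Features(sp[1:80], rep(TRUE, 80), bl$spbm, bl$spba)
  expect_equal(f[["Spldm"]], f[["Splda"]])
  # segment at t = 0: no history, fall back to within-segment breaths
  br0 <- data.frame(t_max_s = 2, t_min_s = 4, t_mid_s = 3, tidal_volume = 0.7)
  bl0 <- rollingBaselines(br0, sp, rep(TRUE, length(sp)), 0, 10)
  expect_equal(bl0$fb, 0.7)
})

test_that("NF drop counts follow the 30/70/85% thresholds", {
  f <- nfFeatures(c(1.0, 0.2, 0.25, 1.0), numeric(80), fb = 1.0)
  expect_equal(f[["Fha"]], 2)   # 0.2, 0.25 dropped > 30%
  expect_equal(f[["Fap"]], 2)   # both dropped > 70%
  expect_equal(f[["Fnor"]], 2)  # the two full breaths
  expect_equal(f[["Fhap"]], 0.5)
  expect_equal(f[["Fapp"]], 0.5)
  expect_equal(f[["Fnorp"]], 0.5)
  # no breaths -> documented all-zero default (never NA)
  z <- nfFeatures(numeric(0), numeric(80), fb = 1.0)
  expect_true(all(z[c("Fmean", "Fstd", "Fran", "Fha", "Fhap", "Fap",
                      "Fapp", "Fnor", "Fnorp")] == 0))
})

test_that("spectral kurtosis peaks for concentrated breathing energy", {
  fs <- 8
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  pure <- sin(2 * pi * 0.3 * t)
  mixed <- pure + 0.8 * sin(2 * pi * 0.25 * t) + 0.8 * sin(2 * pi * 0.35 * t)
  kPure <- nfFeatures(numeric(0), pure, 0)[["Fkur"]]
  kMixed <- nfFeatures(numeric(0), mixed, 0)[["Fkur"]]
  expect_gt(kPure, kMixed)
  # standardized moment: invariant to amplitude scale
  expect_equal(nfFeatures(numeric(0), 10 * pure, 0)[["Fkur"]], kPure)
})

test_that("SpO2 features count desaturation time in seconds", {
  fs <- 8
  sp <- c(rep(90, 4 * fs), rep(94, 6 * fs))
  f <- spo2Features(sp, rep(TRUE, length(sp)), spbm = 97, spba = 96.5, fs)
  expect_equal(f[["Sp92"]], 4)
  expect_equal(f[["Sp91"]], 4)
  expect_equal(f[["Spran"]], 4)
  expect_equal(f[["Spten"]], 4)
  # desaturation levels are baseline minus segment mean
  f2 <- spo2Features(rep(93, 80), rep(TRUE, 80), spbm = 98, spba = 96, fs)
  expect_equal(f2[["Spldm"]], 5)
  expect_equal(f2[["Splda"]], 3)
  # constant at baseline: all zero
  f3 <- spo2Features(rep(97, 80), rep(TRUE, 80), 97, 97, fs)
  expect_true(all(f3[c("Spstd", "Spran", "Spten", "Sp92", "Spdum",
                       "Spldm")] == 0))
})

test_that("time reversal negates Spten and preserves the other SpO2 features", {
  set.seed(21)
  sp <- 97 - cumsum(rnorm(80, sd = 0.3))
  fwd <- spo2Features(sp, rep(TRUE, 80), 97, 96)
  rev <- spo2Features(rev(sp), rep(TRUE, 80), 97, 96)
  expect_equal(rev[["Spten"]], -fwd[["Spten"]])
  for (k in c("Spstd", "Spran", "Sp92", "Sp91", "Spdum", "Spdua", "Spldm"))
    expect_equal(rev[[k]], fwd[[k]])
})

test_that("extraction yields one feature vector per usable segment, deterministically", {
  rec <- generateRecording(synthConfig(duration_s = 120, target_ahi = 0,
                                       artifact_rate = 0, seed = 2))
  seg <- labelSegments(segmentize(rec, 10), annotations(rec))
  sf <- extractFeatures(rec, seg)
  expect_s4_class(sf, "SegmentFeatures")
  expect_equal(ncol(sf), 111)
  expect_equal(nrow(sf), 19)
  sf2 <- extractFeatures(rec, seg)
  expect_identical(SummarizedExperiment::assay(sf, "features"),
                   SummarizedExperiment::assay(sf2, "features"))
})

test_that("apnea segments show larger Fapp and Spldm than normal ones", {
  cfg <- synthConfig(duration_s = 600, target_ahi = 12, apnea_fraction = 1,
                     artifact_rate = 0, seed = 6)
  rec <- generateRecording(cfg)
  pr <- prepareRecording(rec)
  ff <- featureFrame(pr$feat10)
  ah <- ff$label == "AH"
  expect_gt(sum(ah), 0)
  expect_gt(mean(ff$Fapp[ah]), mean(ff$Fapp[!ah]) + 0.2)
  expect_gt(mean(ff$Spldm[ah]), mean(ff$Spldm[!ah]) + 1)
})

test_that("feature tables round trip through CSV with canonical headers", {
  rec <- generateRecording(synthConfig(duration_s = 90, target_ahi = 0,
                                       artifact_rate = 0, seed = 4))
  seg <- labelSegments(segmentize(rec, 10), annotations(rec))
  sf <- extractFeatures(rec, seg)
  path <- withr::local_tempfile(fileext = ".csv")
  writeFeatureTable(sf, path)
  back <- readFeatureTable(path)
  expect_true(all(featureNames() %in% names(back)))
  expect_equal(as.matrix(back[featureNames()]),
               as.matrix(featureFrame(sf)[featureNames()]),
               tolerance = 1e-8, ignore_attr = TRUE)
})
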