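# Shared fixtures, built in code.

# a flat recording with hand-placed annotations, for exact labelling tests
flatRecording <- function(duration_s = 200, ann = NULL, spo2 = 97) {
  n <- duration_s * 8
  Recording(nf = numeric(n), spo2 = rep(spo2, n), sampleRate = 8,
            subjectID = "flat", annotations = ann)
}

# a breathing recording with no events
breathingRecording <- function(duration_s = 120, freq = 0.25, amp = 1) {
  t <- seq(0, duration_s - 1 / 8, by = 1 / 8)
  Recording(nf = amp * sin(2 * pi * freq * t), spo2 = rep(97, length(t)),
            sampleRate = 8, subjectID = "breath")
}

# independent run-length oracle for the event-detector rules: explicit
# index scans, no rle
bruteCorrect <- function(x, min_run = 10, max_gap = 5) {
  x <- ifelse(x == "AH", "AH", "N")
  n <- length(x)
  y <- x
  i <- 1
  while (i <= n) {
    if (x[i] == "AH") {
      j <- i
      while (j < n && x[j + 1] == "AH") j <- j + 1
      if (j - i + 1 < min_run) y[i:j] <- "N"
      i <- j + 1
    } else i <- i + 1
  }
  z <- y
  i <- 1
  while (i <= n) {
    if (y[i] == "N") {
      j <- i
      while (j < n && y[j + 1] == "N") j <- j + 1
      if (i > 1 && j < n && y[i - 1] == "AH" && y[j + 1] == "AH" &&
          (j - i + 1) <= max_gap)
        z[i:j] <- "AH"
      i <- j + 1
    } else i <- i + 1
  }
  z
}

# brute-force union-overlap labelling of one segment (independent of
# labelSegments' interval merging)
bruteOverlap <- function(start, window, ann) {
  grid <- seq(start, start + window, by = 0.001)
  mids <- grid[-1] - 0.0005
  covered <- rep(FALSE, length(mids))
  for (i in seq_len(nrow(ann))) {
    covered <- covered |
      (mids >= ann$onset_s[i] & mids < ann$onset_s[i] + ann$duration_s[i])
  }
  sum(covered) * 0.001
}
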