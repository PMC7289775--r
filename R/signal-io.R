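# Readers/writers for recordings and respiratory-event annotations.
# Canonical internal rate is 8 Hz; slower channels are upsampled by
# sample-and-hold, faster ones mean-decimated, on read.

CANONICAL_RATE <- 8

#' Read a recording from delimited text
#'
#' Expects columns `time_s`, `nf`, `spo2` with a strictly increasing,
#' uniformly spaced time column; the sampling rate is inferred from the
#' spacing.
#'
#' @param path path to a CSV/TSV file (separator auto-detected from the
#'   header line).
#' @param subjectID subject identifier; defaults to the file name.
#' @return A [Recording-class] with an all-true validity mask and no
#'   annotations.
#' @export
readRecordingCSV <- function(path, subjectID = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- detectSep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("time_s", "nf", "spo2")
  if (!all(need %in% names(df)))
    stop("recording file must have columns time_s, nf, spo2")
  t <- df$time_s
  if (length(t) > 1) {
    dt <- diff(t)
    if (any(dt <= 0)) stop("time_s must be strictly increasing")
    if (max(dt) - min(dt) > 1e-6)
      stop("time_s must be uniformly spaced")
    rate <- 1 / stats::median(dt)
  } else {
    rate <- CANONICAL_RATE
  }
  if (is.null(subjectID)) subjectID <- sub("\\.[^.]*$", "", basename(path))
  Recording(nf = df$nf, spo2 = df$spo2, sampleRate = rate,
            subjectID = subjectID)
}

#' Write a recording as delimited text
#'
#' Sample values are written with six decimal places so that a write/read
#' round trip preserves them to 1e-6.
#'
#' @param rec a [Recording-class].
#' @param path output path.
#' @param sep field separator (default comma).
#' @return `path`, invisibly.
#' @export
writeRecordingCSV <- function(rec, path, sep = ",") {
  n <- length(nFlow(rec))
  df <- data.frame(
    time_s = sprintf("%.6f", (seq_len(n) - 1) / sampleRate(rec)),
    nf = sprintf("%.6f", nFlow(rec)),
    spo2 = sprintf("%.6f", oxSat(rec))
  )
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read respiratory-event annotations
#'
#' The native dialect is delimited text with columns `onset_s`, `duration_s`,
#' `label`. `dialect = "ucddb"` accepts the UCDDB respevt-style layout of
#' clock time (`hh:mm:ss`), event type and duration, interpreted relative to
#' `record_start` clock time.
#'
#' Events are returned sorted by onset; overlapping events are preserved.
#'
#' @param path path to the annotation file.
#' @param dialect `"csv"` (default) or `"ucddb"`.
#' @param record_start recording start clock time `"hh:mm:ss"` (ucddb dialect
#'   only).
#' @return data.frame with columns `onset_s`, `duration_s`, `label`.
#' @export
readAnnotations <- function(path, dialect = c("csv", "ucddb"),
                            record_start = "00:00:00") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "csv") {
    first <- readLines(path, n = 1L)
    if (length(first) == 0) {
      ann <- data.frame(onset_s = numeric(), duration_s = numeric(),
                        label = character(), stringsAsFactors = FALSE)
    } else {
      sep <- detectSep(path)
      df <- utils::read.table(path, header = TRUE, sep = sep,
                              stringsAsFactors = FALSE)
      need <- c("onset_s", "duration_s", "label")
      if (!all(need %in% names(df)))
        stop("annotation file must have columns onset_s, duration_s, label")
      ann <- df[need]
    }
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    t0 <- clockToSeconds(record_start)
    rows <- lapply(lines, function(l) {
      f <- strsplit(trimws(l), "[[:space:]]+")[[1]]
      if (length(f) < 3) stop("malformed ucddb annotation line: ", l)
      onset <- clockToSeconds(f[1]) - t0
      if (onset < 0) onset <- onset + 86400  # recording spans midnight
      data.frame(onset_s = onset, duration_s = as.numeric(f[length(f)]),
                 label = paste(f[2:(length(f) - 1)], collapse = "_"),
                 stringsAsFactors = FALSE)
    })
    ann <- do.call(rbind, rows)
    if (is.null(ann))
      ann <- data.frame(onset_s = numeric(), duration_s = numeric(),
                        label = character(), stringsAsFactors = FALSE)
  }
  if (any(ann$duration_s < 0)) stop("negative event duration in ", path)
  ann <- ann[order(ann$onset_s), , drop = FALSE]
  rownames(ann) <- NULL
  ann
}

#' Write respiratory-event annotations
#'
#' Uses the `"csv"` dialect of [readAnnotations()]; a write/read round trip
#' is exact to six decimals.
#'
#' @param ann data.frame with columns `onset_s`, `duration_s`, `label`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAnnotations <- function(ann, path) {
  out <- data.frame(onset_s = sprintf("%.6f", ann$onset_s),
                    duration_s = sprintf("%.6f", ann$duration_s),
                    label = ann$label)
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read NF and SpO2 channels from an EDF file
#'
#' Minimal reader for standard EDF (European Data Format): 256-byte ASCII
#' header, per-signal header blocks, then little-endian int16 data records
#' scaled by the physical/digital calibration. Channels at rates other than
#' 8 Hz are converted on read: slower channels are upsampled by
#' sample-and-hold, faster channels mean-decimated (integer ratios only).
#'
#' @param path path to an EDF file.
#' @param nf_channel label of the nasal-flow channel (default `"Flow"`).
#' @param spo2_channel label of the SpO2 channel (default `"SpO2"`).
#' @return A [Recording-class] at 8 Hz with an all-true validity mask and no
#'   annotations.
#' @export
readEDF <- function(path, nf_channel = "Flow", spo2_channel = "SpO2") {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256, useBytes = TRUE)
  if (nchar(hdr, type = "bytes") < 256) stop("not an EDF file (short header): ", path)
  fld <- function(s, from, len) trimws(substr(s, from, from + len - 1))
  ndr <- as.integer(fld(hdr, 237, 8))
  recdur <- as.numeric(fld(hdr, 245, 8))
  ns <- as.integer(fld(hdr, 253, 4))
  if (is.na(ns) || ns < 1 || is.na(ndr) || ndr < 1)
    stop("not an EDF file (bad header fields): ", path)
  sig <- readChar(con, ns * 256, useBytes = TRUE)
  block <- function(from, len) {
    vapply(seq_len(ns), function(i)
      trimws(substr(sig, from + (i - 1) * len, from + i * len - 1)),
      character(1))
  }
  labels <- block(1, 16)
  off <- ns * 16
  # transducer(80), dim(8) follow; physical/digital min/max next
  pmin <- as.numeric(block(off + ns * 80 + ns * 8 + 1, 8)); off2 <- off + ns * 80 + ns * 8 + ns * 8
  pmax <- as.numeric(block(off2 + 1, 8)); off2 <- off2 + ns * 8
  dmin <- as.numeric(block(off2 + 1, 8)); off2 <- off2 + ns * 8
  dmax <- as.numeric(block(off2 + 1, 8)); off2 <- off2 + ns * 8
  off2 <- off2 + ns * 80  # prefilter
  nspr <- as.integer(block(off2 + 1, 8))

  pick <- function(lab) {
    i <- which(labels == lab)
    if (length(i) == 0)
      stop(sprintf("channel '%s' not found in EDF (available: %s)", lab,
                   paste(labels, collapse = ", ")))
    i[1]
  }
  iNF <- pick(nf_channel)
  iSP <- pick(spo2_channel)

  datNF <- vector("list", ndr)
  datSP <- vector("list", ndr)
  for (r in seq_len(ndr)) {
    for (i in seq_len(ns)) {
      vals <- readBin(con, "integer", n = nspr[i], size = 2,
                      endian = "little", signed = TRUE)
      if (i == iNF) datNF[[r]] <- vals
      if (i == iSP) datSP[[r]] <- vals
    }
  }
  scale <- function(d, i) {
    g <- (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
    pmin[i] + (d - dmin[i]) * g
  }
  nf <- scale(unlist(datNF), iNF)
  sp <- scale(unlist(datSP), iSP)
  rateNF <- nspr[iNF] / recdur
  rateSP <- nspr[iSP] / recdur
  nf <- toCanonicalRate(nf, rateNF)
  sp <- toCanonicalRate(sp, rateSP)
  n <- min(length(nf), length(sp))
  Recording(nf = nf[seq_len(n)], spo2 = sp[seq_len(n)],
            sampleRate = CANONICAL_RATE,
            subjectID = sub("\\.[^.]*$", "", basename(path)))
}

#' Write a recording to an EDF file
#'
#' Companion writer for [readEDF()], mainly for interoperability and
#' fixture construction; both channels are written at the recording's own
#' rate with a 1-s record duration (the recording is truncated to whole
#' seconds).
#'
#' @param rec a [Recording-class].
#' @param path output path.
#' @param nf_channel,spo2_channel channel labels to write.
#' @param spo2_rate rate at which to store the SpO2 channel (default: the
#'   recording's own rate); slower rates subsample, emulating a 1-Hz
#'   oximeter channel.
#' @return `path`, invisibly.
#' @export
writeEDF <- function(rec, path, nf_channel = "Flow", spo2_channel = "SpO2",
                     spo2_rate = sampleRate(rec)) {
  fs <- sampleRate(rec)
  nsec <- floor(length(nFlow(rec)) / fs)
  if (nsec < 1) stop("recording shorter than one EDF record (1 s)")
  k <- fs / spo2_rate
  if (abs(k - round(k)) > 1e-9)
    stop("spo2_rate must divide the recording rate")
  spo2 <- oxSat(rec)[seq(1, nsec * fs, by = as.integer(round(k)))]
  chans <- list(
    list(lab = nf_channel, x = nFlow(rec)[seq_len(nsec * fs)],
         nspr = as.integer(round(fs))),
    list(lab = spo2_channel, x = spo2, nspr = as.integer(round(spo2_rate))))
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(s, w) formatC(as.character(s), width = w, flag = "-")
  wr <- function(s, w) writeChar(pad(s, w), con, nchars = w, eos = NULL)
  wr("0", 8); wr("synthetic", 80); wr("synthetic", 80)
  wr("01.01.26", 8); wr("00.00.00", 8)
  wr(256 * (1 + length(chans)), 8); wr("", 44)
  wr(nsec, 8); wr("1", 8); wr(length(chans), 4)
  for (ch in chans) wr(ch$lab, 16)
  for (ch in chans) wr("", 80)             # transducer
  for (ch in chans) wr("", 8)              # physical dimension
  lims <- lapply(chans, function(ch) {
    lo <- min(ch$x); hi <- max(ch$x)
    if (hi - lo < 1e-9) hi <- lo + 1
    c(lo, hi)
  })
  fmt8 <- function(v) {
    for (f in c("%g", "%.4g", "%.3g", "%.2g")) {
      s <- sprintf(f, v)
      if (nchar(s) <= 8) return(s)
    }
    s
  }
  for (l in lims) wr(fmt8(l[1]), 8)
  for (l in lims) wr(fmt8(l[2]), 8)
  for (ch in chans) wr(dmin, 8)
  for (ch in chans) wr(dmax, 8)
  for (ch in chans) wr("", 80)             # prefiltering
  for (ch in chans) wr(ch$nspr, 8)
  for (ch in chans) wr("", 32)
  dig <- lapply(seq_along(chans), function(i) {
    l <- lims[[i]]
    as.integer(round(dmin + (chans[[i]]$x - l[1]) / (l[2] - l[1]) * (dmax - dmin)))
  })
  for (r in seq_len(nsec)) {
    for (i in seq_along(chans)) {
      np <- chans[[i]]$nspr
      idx <- ((r - 1) * np + 1):(r * np)
      writeBin(dig[[i]][idx], con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

# -- helpers -----------------------------------------------------------------

toCanonicalRate <- function(x, rate) {
  if (abs(rate - CANONICAL_RATE) < 1e-9) return(x)
  if (rate < CANONICAL_RATE) {
    k <- CANONICAL_RATE / rate
    if (abs(k - round(k)) > 1e-9)
      stop("cannot upsample: rate ", rate, " Hz is not an integer divisor of 8 Hz")
    rep(x, each = as.integer(round(k)))        # sample-and-hold
  } else {
    k <- rate / CANONICAL_RATE
    if (abs(k - round(k)) > 1e-9)
      stop("cannot decimate: rate ", rate, " Hz is not an integer multiple of 8 Hz")
    k <- as.integer(round(k))
    n <- floor(length(x) / k)
    colMeans(matrix(x[seq_len(n * k)], nrow = k))  # mean decimation
  }
}

detectSep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

clockToSeconds <- function(s) {
  p <- as.numeric(strsplit(s, ":")[[1]])
  if (length(p) != 3 || any(is.na(p))) stop("bad clock time: ", s)
  p[1] * 3600 + p[2] * 60 + p[3]
}
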