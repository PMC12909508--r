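# Minimal EDF (European Data Format) I/O.
#
# EDF stores an ASCII fixed-width header (256 bytes + 256 per signal)
# followed by data records of 16-bit little-endian integers, scaled
# per-signal between a physical and a digital range.  The writer emits
# one-second data records with identical sampling rate per channel; the
# reader supports exactly that uniform layout (mixed per-channel rates
# are rejected as unsupported).  Seizure annotations travel in a
# tab-separated companion file (onset, offset, lobe, level).

.edfPad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

.edfNum <- function(x, width) .edfPad(format(x, trim = TRUE, digits = 7), width)

#' Write an EEGRecording to an EDF file
#'
#' Serializes the recording as 16-bit EDF with one-second data records and
#' a symmetric physical range per channel.  If the recording carries
#' seizure annotations they are written to `<path>.annotations.txt` as
#' tab-separated `onset  offset  lobe  level` rows.
#'
#' @param recording an [EEGRecording-class].
#' @param path output file path (conventionally `.edf`).
#' @return `path`, invisibly.
#' @seealso [readEDF()]
#' @export
writeEDF <- function(recording, path) {
  stopifnot(is(recording, "EEGRecording"))
  fs <- samplingRate(recording)
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  dat <- eegData(recording)
  nch <- nrow(dat)
  nrec <- floor(ncol(dat) / fs)
  if (nrec < 1) stop("recording shorter than one data record (1 s)")
  used <- seq_len(nrec * fs)

  physMax <- pmax(apply(abs(dat[, used, drop = FALSE]), 1, max), 1)
  physMax <- ceiling(physMax)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edfPad("0", 8), .edfPad("synthetic subject", 80),
    .edfPad("ictalwave recording", 80),
    .edfPad("01.01.00", 8), .edfPad("00.00.00", 8),
    .edfNum(256 + 256 * nch, 8), .edfPad("", 44),
    .edfNum(nrec, 8), .edfNum(1, 8), .edfNum(nch, 4))
  writeChar(hdr, con, eos = NULL)
  fields <- list(
    vapply(channelNames(recording), .edfPad, "", width = 16),
    rep(.edfPad("", 80), nch),
    rep(.edfPad("uV", 8), nch),
    vapply(-physMax, .edfNum, "", width = 8),
    vapply(physMax, .edfNum, "", width = 8),
    rep(.edfNum(-32768, 8), nch),
    rep(.edfNum(32767, 8), nch),
    rep(.edfPad("", 80), nch),
    rep(.edfNum(fs, 8), nch),
    rep(.edfPad("", 32), nch))
  for (f in fields) writeChar(paste(f, collapse = ""), con, eos = NULL)

  scale <- 32767 / physMax
  for (r in seq_len(nrec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    block <- round(dat[, cols, drop = FALSE] * scale)
    block <- pmin(pmax(block, -32768), 32767)
    writeBin(as.integer(t(block)), con, size = 2, endian = "little")
  }

  ann <- annotations(recording)
  if (nrow(ann)) {
    af <- paste0(path, ".annotations.txt")
    out <- data.frame(onset = ann$onset, offset = ann$offset,
                      lobe = if ("lobe" %in% names(ann)) ann$lobe else NA,
                      level = if ("level" %in% names(ann)) ann$level else NA)
    utils::write.table(out, af, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read an EDF file into an EEGRecording
#'
#' Parses the EDF header and 16-bit data records, rescaling each channel
#' to its physical (microvolt) range.  If `<path>.annotations.txt` exists
#' it is loaded as seizure annotations; intervals outside the record
#' duration raise a validation error.  Mixed per-channel sampling rates
#' are not supported.
#'
#' @param path EDF file path.
#' @return an [EEGRecording-class].
#' @export
readEDF <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  readChar(con, 8, useBytes = TRUE)                       # version
  readChar(con, 160, useBytes = TRUE)                     # patient + recording
  readChar(con, 16, useBytes = TRUE)                      # date + time
  hdrBytes <- suppressWarnings(as.integer(readChar(con, 8, useBytes = TRUE)))
  readChar(con, 44, useBytes = TRUE)
  nrec <- suppressWarnings(as.integer(readChar(con, 8, useBytes = TRUE)))
  recDur <- suppressWarnings(as.numeric(readChar(con, 8, useBytes = TRUE)))
  nch <- suppressWarnings(as.integer(readChar(con, 4, useBytes = TRUE)))
  if (is.na(nch) || is.na(nrec) || is.na(hdrBytes))
    stop("malformed EDF header")
  if (nch < 1) stop("EDF parse error: file declares 0 channels")

  rdChar <- function(w) vapply(seq_len(nch), function(i)
    trimws(readChar(con, w, useBytes = TRUE)), "")
  labels <- rdChar(16)
  rdChar(80)                                              # transducer
  rdChar(8)                                               # physical dim
  physMin <- as.numeric(rdChar(8))
  physMax <- as.numeric(rdChar(8))
  digMin <- as.numeric(rdChar(8))
  digMax <- as.numeric(rdChar(8))
  rdChar(80)                                              # prefiltering
  spr <- as.integer(rdChar(8))
  rdChar(32)
  if (any(is.na(c(physMin, physMax, digMin, digMax, spr))))
    stop("malformed EDF signal header")
  if (length(unique(spr)) != 1L)
    stop("unsupported EDF: mixed per-channel sampling rates")
  fs <- spr[1] / recDur

  dat <- matrix(0, nch, nrec * spr[1])
  for (r in seq_len(nrec)) {
    raw <- readBin(con, integer(), n = nch * spr[1], size = 2,
                   signed = TRUE, endian = "little")
    block <- matrix(raw, nrow = spr[1], ncol = nch)
    cols <- ((r - 1) * spr[1] + 1):(r * spr[1])
    dat[, cols] <- t(block)
  }
  gain <- (physMax - physMin) / (digMax - digMin)
  dat <- dat * gain + (physMin - digMin * gain)

  ann <- data.frame(onset = numeric(0), offset = numeric(0),
                    label = character(0), stringsAsFactors = FALSE)
  af <- paste0(path, ".annotations.txt")
  if (file.exists(af)) {
    tab <- utils::read.table(af, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    dur <- ncol(dat) / fs
    if (any(tab$onset < 0) || any(tab$offset > dur + 1e-9))
      stop("annotation interval outside record duration")
    ann <- data.frame(onset = tab$onset, offset = tab$offset,
                      label = "seizure", lobe = tab$lobe, level = tab$level,
                      stringsAsFactors = FALSE)
  }
  new("EEGRecording", data = dat, samplingRate = fs,
      channelNames = labels, annotations = ann)
}
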