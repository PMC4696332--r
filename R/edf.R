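# Minimal EDF (European Data Format) support for continuous 16-bit
# recordings. EDF is a fixed-layout format: a 256-byte ASCII header, 256
# ASCII bytes per signal, then data records of little-endian int16 samples
# scaled linearly between the digital and physical ranges. Only the subset
# needed for resting-state EEG is implemented: equal sampling rate across
# signals, no annotations, no discontinuous (EDF+D) files.

.edfField <- function(con, nchars) {
  trimws(readChar(con, nchars, useBytes = TRUE))
}

.readEdf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  version <- .edfField(con, 8)
  if (version != "0")
    stop("not an EDF file (version field '", version, "'): ", path)
  readChar(con, 80 + 80 + 8 + 8, useBytes = TRUE)   # patient/recording ids, date, time
  .edfField(con, 8)                                  # header byte count
  .edfField(con, 44)                                 # reserved
  nrec <- as.integer(.edfField(con, 8))
  recDur <- as.numeric(.edfField(con, 8))
  ns <- as.integer(.edfField(con, 4))
  if (is.na(ns) || ns < 1) stop("EDF header declares no signals: ", path)
  if (is.na(nrec) || nrec < 1) stop("EDF header declares no data records: ", path)

  readNsField <- function(nchars)
    vapply(seq_len(ns), function(i) .edfField(con, nchars), character(1))
  labels <- readNsField(16)
  readNsField(80)                                    # transducer
  readNsField(8)                                     # physical dimension
  physMin <- as.numeric(readNsField(8))
  physMax <- as.numeric(readNsField(8))
  digMin <- as.numeric(readNsField(8))
  digMax <- as.numeric(readNsField(8))
  readNsField(80)                                    # prefiltering
  spr <- as.integer(readNsField(8))                  # samples per record
  readNsField(32)                                    # reserved

  if (length(unique(spr)) != 1L)
    stop("EDF signals with unequal sampling rates are not supported: ", path)
  if (recDur <= 0) stop("EDF record duration must be positive: ", path)
  fs <- spr[1] / recDur

  raw <- readBin(con, "integer", n = nrec * ns * spr[1], size = 2,
                 signed = TRUE, endian = "little")
  if (length(raw) != nrec * ns * spr[1])
    stop("EDF data section truncated: ", path)
  # records x (signal-major within record) -> channels x time
  dim(raw) <- c(spr[1], ns, nrec)
  samples <- matrix(0, ns, spr[1] * nrec)
  scale <- (physMax - physMin) / (digMax - digMin)
  for (s in seq_len(ns)) {
    x <- as.numeric(raw[, s, ])
    samples[s, ] <- (x - digMin[s]) * scale[s] + physMin[s]
  }
  rownames(samples) <- labels
  list(samples = samples, fs = fs, channels = labels)
}

.edfPad <- function(x, nchars) {
  x <- as.character(x)
  if (nchar(x, type = "bytes") > nchars) x <- substr(x, 1, nchars)
  formatC(x, width = -nchars)
}

.edfNum <- function(x, nchars) {
  s <- formatC(x, format = "g", digits = 7, width = -1)
  if (nchar(s) > nchars) s <- substr(s, 1, nchars)
  .edfPad(s, nchars)
}

#' Write a recording to an EDF file
#'
#' Writes a continuous 16-bit EDF file with one-second data records. The
#' physical range of each signal is taken from its data range, so the
#' quantization error is at most (max - min)/65534 microvolts per sample.
#' The recording is truncated to a whole number of seconds.
#'
#' @param rec an [EEGRecording-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [readRecording()]
#' @export
writeEdf <- function(rec, path) {
  stopifnot(is(rec, "EEGRecording"))
  fs <- rec@fs
  if (abs(fs - round(fs)) > 1e-9)
    stop("writeEdf requires an integer sampling rate")
  fs <- as.integer(round(fs))
  nrec <- floor(ncol(rec@samples) / fs)
  if (nrec < 1) stop("recording shorter than one EDF data record (1 s)")
  x <- rec@samples[, seq_len(nrec * fs), drop = FALSE]
  ns <- nrow(x)

  physMin <- apply(x, 1, min)
  physMax <- apply(x, 1, max)
  flat <- physMax - physMin < 1e-12
  physMin[flat] <- physMin[flat] - 1
  physMax[flat] <- physMax[flat] + 1
  digMin <- -32768; digMax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, eos = NULL, useBytes = TRUE)
  wr(.edfPad("0", 8))
  wr(.edfPad("X X X X", 80))                         # local patient id
  wr(.edfPad("Startdate X X X X", 80))               # local recording id
  wr(.edfPad("01.01.01", 8)); wr(.edfPad("00.00.00", 8))
  wr(.edfPad(256 * (1 + ns), 8))
  wr(.edfPad("", 44))
  wr(.edfPad(nrec, 8)); wr(.edfPad(1, 8)); wr(.edfPad(ns, 4))
  for (lab in rec@channels) wr(.edfPad(paste("EEG", lab), 16))
  for (i in seq_len(ns)) wr(.edfPad("AgAgCl electrode", 80))
  for (i in seq_len(ns)) wr(.edfPad("uV", 8))
  for (i in seq_len(ns)) wr(.edfNum(physMin[i], 8))
  for (i in seq_len(ns)) wr(.edfNum(physMax[i], 8))
  for (i in seq_len(ns)) wr(.edfPad(digMin, 8))
  for (i in seq_len(ns)) wr(.edfPad(digMax, 8))
  for (i in seq_len(ns)) wr(.edfPad("", 80))
  for (i in seq_len(ns)) wr(.edfPad(fs, 8))
  for (i in seq_len(ns)) wr(.edfPad("", 32))

  scale <- (digMax - digMin) / (physMax - physMin)
  for (r in seq_len(nrec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    for (s in seq_len(ns)) {
      dig <- round((x[s, cols] - physMin[s]) * scale[s] + digMin)
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}
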