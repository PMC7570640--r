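# Minimal European Data Format (EDF) I/O: 256-byte fixed header, 256 bytes
# per signal, 16-bit little-endian samples, one-second data records. Covers
# what the pipeline needs (continuous multichannel recordings with integer
# per-second sampling rates); not a general EDF+ implementation.

.edfPad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording as EDF
#'
#' Encodes the signal as 16-bit integers in one-second data records, with
#' the physical range taken per channel from the data (so quantisation
#' error is at most range/65535 per sample). The class label travels in
#' the EDF recording-identification field as \code{label=<label>}. Trailing
#' samples that do not fill a whole record are dropped.
#'
#' @param recording a \linkS4class{RawRecording} with integer \code{fs}.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
writeRecordingEDF <- function(recording, path) {
  sig <- eegSignal(recording)
  fs <- samplingRate(recording)
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  ns <- nrow(sig)
  nrec <- floor(ncol(sig) / fs)
  if (nrec < 1) stop("recording shorter than one data record (1 s)")
  sig <- sig[, seq_len(nrec * fs), drop = FALSE]

  pmin <- apply(sig, 1, min)
  pmax <- apply(sig, 1, max)
  flat <- pmax - pmin < 1e-9
  pmin[flat] <- pmin[flat] - 1
  pmax[flat] <- pmax[flat] + 1

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(.edfPad(x, width), con, width,
                                     eos = NULL)
  wr("0", 8)
  wr(recordingId(recording), 80)
  wr(paste0("label=", classLabel(recording)), 80)
  wr("01.01.20", 8)
  wr("00.00.00", 8)
  wr(256 * (1 + ns), 8)
  wr("", 44)
  wr(nrec, 8)
  wr(1, 8)
  wr(ns, 4)
  for (f in list(function(i) channelNames(recording)[i])) # labels, 16 bytes
    for (i in seq_len(ns)) wr(f(i), 16)
  for (i in seq_len(ns)) wr("", 80)             # transducer
  for (i in seq_len(ns)) wr("uV", 8)            # physical dimension
  for (i in seq_len(ns)) wr(signif(pmin[i], 7), 8)
  for (i in seq_len(ns)) wr(signif(pmax[i], 7), 8)
  for (i in seq_len(ns)) wr(-32768, 8)
  for (i in seq_len(ns)) wr(32767, 8)
  for (i in seq_len(ns)) wr("", 80)             # prefiltering
  for (i in seq_len(ns)) wr(fs, 8)              # samples per record
  for (i in seq_len(ns)) wr("", 32)

  gain <- (pmax - pmin) / 65535
  for (r in seq_len(nrec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (i in seq_len(ns)) {
      dig <- round((sig[i, idx] - pmin[i]) / gain[i]) - 32768
      writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

.edfReadStr <- function(con, width) trimws(readChar(con, width, TRUE))

#' Read an EDF recording
#'
#' Parses the fixed-width EDF headers and 16-bit samples back into a
#' \linkS4class{RawRecording} in physical units. When the file carries 64
#' channels including CPz, CPz is dropped (it is the EOG channel of this
#' montage); any other channel count different from 63 is rejected unless
#' \code{channels} selects the selection to keep or \code{strict = FALSE}.
#'
#' @param path EDF file.
#' @param channels optional character vector of channel labels to keep.
#' @param strict require 63 channels after selection (default on).
#' @return A \linkS4class{RawRecording}.
#' @export
readRecordingEDF <- function(path, channels = NULL, strict = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) .edfReadStr(con, w)
  rd(8)                      # version
  id <- rd(80)
  recfield <- rd(80)
  rd(8); rd(8); rd(8); rd(44)
  nrec <- as.integer(rd(8))
  recDur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  pmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1)
    stop("mixed per-signal sampling rates are not supported")
  fs <- spr[1] / recDur

  sig <- matrix(0, ns, nrec * spr[1])
  for (r in seq_len(nrec)) {
    for (i in seq_len(ns)) {
      raw <- readBin(con, "integer", spr[i], size = 2, endian = "little")
      gain <- (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
      sig[i, ((r - 1) * spr[i] + 1):(r * spr[i])] <-
        pmin[i] + (raw - dmin[i]) * gain
    }
  }

  keep <- seq_len(ns)
  if (!is.null(channels)) {
    keep <- match(channels, labels)
    if (anyNA(keep)) stop("channels not present: ",
                          paste(channels[is.na(keep)], collapse = ", "))
  } else if (ns == 64 && "CPz" %in% labels) {
    keep <- which(labels != "CPz")
  }
  if (strict && length(keep) != 63)
    stop("expected 63 channels after selection, got ", length(keep),
         "; pass `channels` or strict = FALSE")
  label <- if (grepl("label=", recfield))
    sub(".*label=([a-z]+).*", "\\1", recfield) else NA_character_
  if (!is.na(label) && !label %in% .classLevels) label <- NA_character_
  rawRecording(sig[keep, , drop = FALSE], fs = fs,
               channelNames = labels[keep], label = label, id = id)
}
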