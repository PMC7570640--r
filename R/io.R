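# Plain-text array-file I/O: a channels x samples CSV per recording with a
# JSON metadata sidecar, a labels.csv table per dataset directory, and
# feature tables (id,label,v1..vH).

#' Write a recording as a CSV array file
#'
#' Writes \code{<id>.csv} (one row per channel, first column the channel
#' label) and \code{<id>.json} (sampling rate, label, id) into \code{dir}.
#'
#' @param recording a \linkS4class{RawRecording}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the CSV path.
#' @export
writeRecordingCSV <- function(recording, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(dir, recordingId(recording))
  df <- data.frame(channel = channelNames(recording),
                   eegSignal(recording), check.names = FALSE)
  utils::write.csv(df, paste0(base, ".csv"), row.names = FALSE)
  jsonlite::write_json(list(fs = samplingRate(recording),
                            label = classLabel(recording),
                            id = recordingId(recording)),
                       paste0(base, ".json"), auto_unbox = TRUE)
  invisible(paste0(base, ".csv"))
}

.readRecordingCSV <- function(path) {
  meta <- jsonlite::read_json(sub("\\.csv$", ".json", path),
                              simplifyVector = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  sig <- as.matrix(df[, -1, drop = FALSE])
  dimnames(sig) <- NULL
  rawRecording(sig, fs = meta$fs, channelNames = df$channel,
               label = if (is.null(meta$label)) NA_character_ else meta$label,
               id = meta$id)
}

#' Read a recording from EDF or CSV
#'
#' Dispatches on file extension: \code{.edf} via
#' \code{\link{readRecordingEDF}}, \code{.csv} via the array-file reader
#' (which expects a \code{.json} sidecar with the sampling rate).
#'
#' @param path file path.
#' @param ... passed to the format-specific reader.
#' @return A \linkS4class{RawRecording}.
#' @export
readRecording <- function(path, ...) {
  if (!file.exists(path)) stop("no such file: ", path)
  switch(tolower(tools::file_ext(path)),
         edf = readRecordingEDF(path, ...),
         csv = .readRecordingCSV(path),
         stop("unsupported format: ", path))
}

#' Write a dataset with its label table
#'
#' Writes every recording into \code{dir} (CSV array files or EDF) plus a
#' \code{labels.csv} sidecar with columns \code{recording_id,label}.
#'
#' @param recordings list of \linkS4class{RawRecording}s.
#' @param dir output directory.
#' @param format \code{"csv"} or \code{"edf"}.
#' @return Invisibly, \code{dir}.
#' @export
writeDataset <- function(recordings, dir, format = c("csv", "edf")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rec in recordings) {
    if (format == "csv") writeRecordingCSV(rec, dir)
    else writeRecordingEDF(rec, file.path(dir,
                                          paste0(recordingId(rec), ".edf")))
  }
  utils::write.csv(
    data.frame(recording_id = vapply(recordings, recordingId, character(1)),
               label = vapply(recordings, classLabel, character(1))),
    file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}

#' Write / read a feature table
#'
#' Feature tables are CSV files with columns \code{id}, \code{label},
#' \code{v1..vH}, the interchange format between the LSTM feature
#' extractor and the ECOC-SVM tools.
#'
#' @param features feature matrix from \code{\link{extractFeatures}}.
#' @param path CSV path.
#' @return \code{writeFeaturesCSV}: invisibly, \code{path};
#'   \code{readFeaturesCSV}: a feature matrix with a \code{"labels"}
#'   attribute.
#' @export
writeFeaturesCSV <- function(features, path) {
  df <- data.frame(id = rownames(features),
                   label = attr(features, "labels"), features)
  names(df)[-(1:2)] <- paste0("v", seq_len(ncol(features)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeaturesCSV
#' @export
readFeaturesCSV <- function(path) {
  df <- utils::read.csv(path)
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  dimnames(m) <- list(df$id, NULL)
  attr(m, "labels") <- df$label
  m
}

#' Write a bootstrap report
#'
#' Writes the replicate table as CSV and the metric summaries (plus
#' protocol settings) as JSON.
#'
#' @param report a \linkS4class{BootstrapReport}.
#' @param dir output directory.
#' @param prefix file-name prefix (default \code{"report"}).
#' @return Invisibly, \code{dir}.
#' @export
writeReport <- function(report, dir, prefix = "report") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(replicates(report),
                   file.path(dir, paste0(prefix, "_replicates.csv")),
                   row.names = FALSE)
  s <- metricSummary(report)
  jsonlite::write_json(
    list(nBootstrap = report@nBootstrap, kFolds = report@kFolds,
         seed = report@seed,
         metrics = cbind(metric = rownames(s), s)),
    file.path(dir, paste0(prefix, "_summary.json")),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
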