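#' Accessors for tbiEEG classes
#'
#' Small accessor generics so user code never touches slots directly:
#' \code{eegSignal} (channels x samples matrix), \code{samplingRate},
#' \code{channelNames}, \code{classLabel}, \code{recordingId},
#' \code{stepData} (steps x channels x samples array), \code{asStepMatrix}
#' (channels x time matrix with steps re-concatenated), \code{nSteps},
#' \code{designMatrix}, \code{hiddenUnits}, \code{lossTrace},
#' \code{replicates} and \code{metricSummary}.
#'
#' @param object an object of the corresponding tbiEEG class.
#' @return The accessed component (see each method's class documentation).
#' @name accessors
#' @aliases eegSignal samplingRate channelNames classLabel recordingId
#'   stepData asStepMatrix nSteps designMatrix hiddenUnits lossTrace
#'   replicates metricSummary
NULL

#' @rdname accessors
#' @export
setGeneric("eegSignal", function(object) standardGeneric("eegSignal"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setGeneric("classLabel", function(object) standardGeneric("classLabel"))
#' @rdname accessors
#' @export
setGeneric("recordingId", function(object) standardGeneric("recordingId"))
#' @rdname accessors
#' @export
setGeneric("stepData", function(object) standardGeneric("stepData"))
#' @rdname accessors
#' @export
setGeneric("asStepMatrix", function(object) standardGeneric("asStepMatrix"))
#' @rdname accessors
#' @export
setGeneric("nSteps", function(object) standardGeneric("nSteps"))
#' @rdname accessors
#' @export
setGeneric("designMatrix", function(object) standardGeneric("designMatrix"))
#' @rdname accessors
#' @export
setGeneric("hiddenUnits", function(object) standardGeneric("hiddenUnits"))
#' @rdname accessors
#' @export
setGeneric("lossTrace", function(object) standardGeneric("lossTrace"))
#' @rdname accessors
#' @export
setGeneric("replicates", function(object) standardGeneric("replicates"))
#' @rdname accessors
#' @export
setGeneric("metricSummary", function(object) standardGeneric("metricSummary"))
#' @rdname accessors
#' @export
setGeneric("maskIntervals", function(object) standardGeneric("maskIntervals"))

#' @rdname accessors
setMethod("eegSignal", "RawRecording", function(object) object@signal)
#' @rdname accessors
setMethod("samplingRate", "RawRecording", function(object) object@fs)
#' @rdname accessors
setMethod("channelNames", "RawRecording", function(object) object@channelNames)
#' @rdname accessors
setMethod("classLabel", "RawRecording", function(object) object@label)
#' @rdname accessors
setMethod("recordingId", "RawRecording", function(object) object@id)

#' @rdname accessors
setMethod("stepData", "StepSequence", function(object) object@data)
#' @rdname accessors
setMethod("classLabel", "StepSequence", function(object) object@label)
#' @rdname accessors
setMethod("recordingId", "StepSequence", function(object) object@id)
#' @rdname accessors
setMethod("nSteps", "StepSequence", function(object) dim(object@data)[1])

#' @rdname accessors
setMethod("asStepMatrix", "StepSequence", function(object) {
  d <- dim(object@data)  # steps x channels x samples
  out <- matrix(0, d[2], d[1] * d[3])
  for (k in seq_len(d[1]))
    out[, ((k - 1) * d[3] + 1):(k * d[3])] <-
      matrix(object@data[k, , ], d[2], d[3])
  out
})

#' @rdname accessors
setMethod("maskIntervals", "ArtifactMask", function(object) object@intervals)

#' @rdname accessors
setMethod("designMatrix", "CodingDesign", function(object) object@design)
#' @rdname accessors
setMethod("designMatrix", "EcocModel", function(object) object@design@design)

#' @rdname accessors
setMethod("hiddenUnits", "LSTMModel", function(object) ncol(object@R))
#' @rdname accessors
setMethod("lossTrace", "LSTMModel", function(object) object@trace)

#' @rdname accessors
setMethod("replicates", "BootstrapReport", function(object) object@replicates)
#' @rdname accessors
setMethod("metricSummary", "BootstrapReport", function(object) object@summary)

setMethod("show", "RawRecording", function(object) {
  cat(sprintf("RawRecording '%s': %d channels x %d samples @ %g Hz (%.1f s)\n",
              object@id, nrow(object@signal), ncol(object@signal),
              object@fs, ncol(object@signal) / object@fs))
  cat(sprintf("  label: %s; artifact bursts logged: %d\n",
              object@label, nrow(object@artifacts)))
})

setMethod("show", "StepSequence", function(object) {
  d <- dim(object@data)
  cat(sprintf("StepSequence '%s': %d steps x %d channels x %d samples (label: %s)\n",
              object@id, d[1], d[2], d[3], object@label))
})

setMethod("show", "ArtifactMask", function(object) {
  cat(sprintf("ArtifactMask: %d interval(s), %.2f s total\n",
              nrow(object@intervals),
              sum(object@intervals[, 2] - object@intervals[, 1])))
})

setMethod("show", "LSTMModel", function(object) {
  cat(sprintf("LSTMModel: %d hidden units, input dim %d, %d classes\n",
              ncol(object@R), ncol(object@W), nrow(object@Wy)))
  if (length(object@trace))
    cat(sprintf("  trained %d epochs; final mean loss %.4f\n",
                length(object@trace), object@trace[length(object@trace)]))
})

setMethod("show", "CodingDesign", function(object) {
  cat("CodingDesign (rows = classes, columns = binary learners):\n")
  print(object@design)
})

setMethod("show", "EcocModel", function(object) {
  cat(sprintf("EcocModel: %d binary learners over classes %s\n",
              length(object@learners), paste(object@classes, collapse = ", ")))
})

setMethod("show", "BootstrapReport", function(object) {
  cat(sprintf("BootstrapReport: %d replicates, %d-fold CV (seed %s)\n",
              object@nBootstrap, object@kFolds, format(object@seed)))
  s <- object@summary
  for (m in rownames(s))
    cat(sprintf("  %-11s %6.2f +/- %.2f  [%.2f, %.2f]\n", m, s[m, "mean"],
                s[m, "sd"], s[m, "ci_lower"], s[m, "ci_upper"]))
})
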