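#' @import methods
NULL

.classLevels <- c("healthy", "mild", "moderate")

#' Class labels of the three-group problem
#'
#' The classifier distinguishes healthy controls from mild and moderate
#' traumatic brain injury (TBI). Labels are always reported in this fixed
#' order; ties in Hamming decoding are broken towards the earlier label.
#'
#' @return Character vector \code{c("healthy", "mild", "moderate")}.
#' @export
#' @examples
#' tbiClasses()
tbiClasses <- function() .classLevels

#' RawRecording: a labelled multichannel EEG signal
#'
#' Container for one discrete multichannel recording \eqn{d_i[n] = a_i(n/Fs)}:
#' a channels-by-samples matrix in microvolts together with its sampling
#' rate, montage labels and (optionally) a class label. The canonical
#' resting-state recording has 63 channels (10-10 montage with CPz excluded,
#' CPz being the EOG channel) sampled at 1000 Hz, but the class itself
#' admits any channel count so that components can be exercised on small
#' signals.
#'
#' @slot signal numeric matrix, channels x samples, microvolts.
#' @slot fs sampling rate in Hz.
#' @slot channelNames one label per row of \code{signal}.
#' @slot label class label (\code{"healthy"}, \code{"mild"},
#'   \code{"moderate"}) or \code{NA} when unknown.
#' @slot id recording identifier.
#' @slot artifacts data frame with columns \code{start}, \code{end}
#'   (seconds): ground-truth artifact burst locations when the recording was
#'   simulated; empty otherwise.
#' @exportClass RawRecording
setClass("RawRecording",
  representation(signal = "matrix", fs = "numeric",
                 channelNames = "character", label = "character",
                 id = "character", artifacts = "data.frame"),
  prototype(fs = 1000, label = NA_character_, id = "",
            artifacts = data.frame(start = numeric(0), end = numeric(0))))

setValidity("RawRecording", function(object) {
  msg <- character(0)
  if (!is.numeric(object@signal) || nrow(object@signal) < 1 ||
      ncol(object@signal) < 1)
    msg <- c(msg, "signal must be a non-empty numeric matrix")
  if (length(object@fs) != 1 || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (length(object@channelNames) != nrow(object@signal))
    msg <- c(msg, "channelNames must match the number of signal rows")
  if (!is.na(object@label) && !object@label %in% .classLevels)
    msg <- c(msg, sprintf("label must be one of %s",
                          paste(.classLevels, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a RawRecording
#'
#' @param signal channels x samples numeric matrix (microvolts).
#' @param fs sampling rate, Hz.
#' @param channelNames channel labels; defaults to \code{Ch1..ChK}, or the
#'   63-channel 10-10 montage when the matrix has 63 rows.
#' @param label optional class label.
#' @param id recording identifier.
#' @param artifacts optional data frame of ground-truth artifact intervals.
#' @return A \linkS4class{RawRecording}.
#' @export
#' @examples
#' rec <- rawRecording(matrix(rnorm(200), 2), fs = 100)
#' samplingRate(rec)
rawRecording <- function(signal, fs, channelNames = NULL,
                         label = NA_character_, id = "rec",
                         artifacts = NULL) {
  signal <- as.matrix(signal)
  if (is.null(channelNames)) {
    channelNames <- if (nrow(signal) == 63) montage1010()
                    else paste0("Ch", seq_len(nrow(signal)))
  }
  if (is.null(artifacts))
    artifacts <- data.frame(start = numeric(0), end = numeric(0))
  new("RawRecording", signal = signal, fs = fs,
      channelNames = channelNames, label = as.character(label), id = id,
      artifacts = artifacts)
}

#' ArtifactMask: intervals to excise from a recording
#'
#' Half-open time intervals \code{[start, end)} in seconds, sorted and
#' non-overlapping, on the time axis of the recording they will be applied
#' to (after decimation, in the canonical chain).
#'
#' @slot intervals two-column numeric matrix (start, end), seconds.
#' @exportClass ArtifactMask
setClass("ArtifactMask", representation(intervals = "matrix"),
         prototype(intervals = matrix(numeric(0), ncol = 2)))

setValidity("ArtifactMask", function(object) {
  iv <- object@intervals
  if (ncol(iv) != 2) return("intervals must have two columns (start, end)")
  if (nrow(iv) == 0) return(TRUE)
  if (any(!is.finite(iv))) return("intervals must be finite")
  if (any(iv[, 1] < 0)) return("interval starts must be >= 0")
  if (any(iv[, 2] <= iv[, 1])) return("intervals must satisfy start < end")
  if (nrow(iv) > 1 && any(iv[-1, 1] < iv[-nrow(iv), 2]))
    return("intervals must be sorted and non-overlapping")
  TRUE
})

#' Construct an ArtifactMask
#'
#' @param start,end numeric vectors of interval bounds in seconds
#'   (half-open \code{[start, end)}).
#' @return An \linkS4class{ArtifactMask}.
#' @export
#' @examples
#' artifactMask(c(10, 30), c(12, 31.5))
artifactMask <- function(start = numeric(0), end = numeric(0)) {
  iv <- cbind(start = as.numeric(start), end = as.numeric(end))
  if (nrow(iv) > 1) iv <- iv[order(iv[, 1]), , drop = FALSE]
  new("ArtifactMask", intervals = iv)
}

#' StepSequence: one pre-processed recording as an LSTM input sequence
#'
#' A three-dimensional array of steps x channels x samples. The canonical
#' pre-processed recording is 60 steps x 63 channels x 100 samples: one
#' second of 100 Hz signal per step, i.e. a 63 x 6000 matrix cut into 60
#' consecutive one-second blocks.
#'
#' @slot data numeric array, steps x channels x samples.
#' @slot label class label or \code{NA}.
#' @slot id identifier.
#' @exportClass StepSequence
setClass("StepSequence",
  representation(data = "array", label = "character", id = "character"),
  prototype(label = NA_character_, id = ""))

setValidity("StepSequence", function(object) {
  d <- dim(object@data)
  if (length(d) != 3 || any(d < 1))
    return("data must be a steps x channels x samples array")
  if (!is.na(object@label) && !object@label %in% .classLevels)
    return("label must be healthy, mild or moderate")
  TRUE
})

#' Construct a StepSequence
#'
#' @param data steps x channels x samples numeric array.
#' @param label optional class label.
#' @param id identifier.
#' @return A \linkS4class{StepSequence}.
#' @export
stepSequence <- function(data, label = NA_character_, id = "seq") {
  new("StepSequence", data = data, label = as.character(label), id = id)
}

#' LSTMModel: a trained (or freshly initialised) single-cell LSTM
#'
#' Gate weights follow the standard formulation with logistic forget (f),
#' input (i) and output (o) gates and a tanh cell-candidate gate (s): rows
#' of \code{W}, \code{R}, \code{b} are stacked gate blocks (f, i, s, o) of
#' \code{H} rows each. A fully connected softmax head with one neuron per
#' class sits on the final hidden state. Per-channel standardisation
#' statistics estimated on the training set travel with the model.
#'
#' @slot W input weights, 4H x D (D = channels x samples per step).
#' @slot R recurrent weights, 4H x H.
#' @slot b biases, length 4H.
#' @slot Wy head weights, K x H.
#' @slot by head biases, length K.
#' @slot classes class labels in head order.
#' @slot normCenter,normScale per-channel standardisation statistics
#'   (length = channel count; length 0 when not fitted).
#' @slot trace mean training loss per epoch.
#' @slot config training configuration used (list).
#' @exportClass LSTMModel
setClass("LSTMModel",
  representation(W = "matrix", R = "matrix", b = "numeric", Wy = "matrix",
                 by = "numeric", classes = "character",
                 normCenter = "numeric", normScale = "numeric",
                 trace = "numeric", config = "list"),
  prototype(classes = .classLevels, normCenter = numeric(0),
            normScale = numeric(0), trace = numeric(0), config = list()))

setValidity("LSTMModel", function(object) {
  H <- ncol(object@R)
  msg <- character(0)
  if (nrow(object@W) != 4 * H || nrow(object@R) != 4 * H ||
      length(object@b) != 4 * H)
    msg <- c(msg, "W, R, b must have 4H rows/elements")
  if (ncol(object@Wy) != H || length(object@by) != nrow(object@Wy))
    msg <- c(msg, "head dimensions inconsistent with H")
  if (!all(is.finite(object@W)) || !all(is.finite(object@R)) ||
      !all(is.finite(object@b)) || !all(is.finite(object@Wy)) ||
      !all(is.finite(object@by)))
    msg <- c(msg, "all parameters must be finite")
  if (length(msg)) msg else TRUE
})

#' CodingDesign: an error-correcting output code matrix
#'
#' Rows are class codewords over \{-1, 0, +1\}; columns are binary learners.
#' Each column must oppose at least one positive and one negative class and
#' rows must be distinct and not all-zero.
#'
#' @slot design integer matrix, classes x learners, entries in \{-1,0,1\}.
#' @exportClass CodingDesign
setClass("CodingDesign", representation(design = "matrix"))

setValidity("CodingDesign", function(object) {
  M <- object@design
  if (!all(M %in% c(-1, 0, 1)))
    return("design entries must be -1, 0 or 1")
  if (!all(apply(M, 2, function(col) any(col == 1) && any(col == -1))))
    return("every column needs at least one +1 and one -1")
  if (any(rowSums(abs(M)) == 0)) return("no all-zero rows allowed")
  if (anyDuplicated(apply(M, 1, paste, collapse = ",")))
    return("rows must be distinct")
  TRUE
})

#' Construct a CodingDesign
#'
#' @param design classes x learners matrix over \{-1, 0, 1\}; row names are
#'   class labels, column names learner labels.
#' @return A \linkS4class{CodingDesign}.
#' @seealso \code{\link{defaultDesign}} for the one-vs-one design used by
#'   the architecture.
#' @export
codingDesign <- function(design) {
  design <- as.matrix(design)
  if (is.null(rownames(design)))
    rownames(design) <- .classLevels[seq_len(nrow(design))]
  if (is.null(colnames(design)))
    colnames(design) <- paste0("SVM", seq_len(ncol(design)))
  new("CodingDesign", design = design)
}

#' EcocModel: trained ECOC-SVM multiclass classifier
#'
#' One binary margin classifier per design column, plus the feature
#' standardisation fitted on the training features.
#'
#' @slot design the \linkS4class{CodingDesign}.
#' @slot learners list of fitted binary SVMs (one per design column).
#' @slot center,scale feature standardisation statistics.
#' @slot classes class labels (design row order).
#' @exportClass EcocModel
setClass("EcocModel",
  representation(design = "CodingDesign", learners = "list",
                 center = "numeric", scale = "numeric",
                 classes = "character"))

setValidity("EcocModel", function(object) {
  if (length(object@learners) != ncol(object@design@design))
    return("learner count must equal design columns")
  TRUE
})

#' BootstrapReport: replicate-level metrics and their summaries
#'
#' One row per bootstrap replicate with pooled 3-fold cross-validation
#' metrics in percent, plus per-metric mean, standard deviation and 95\%
#' percentile confidence interval.
#'
#' @slot replicates data frame with columns \code{replicate},
#'   \code{accuracy}, \code{sensitivity}, \code{specificity},
#'   \code{precision} (percent).
#' @slot summary data frame with one row per metric: \code{mean},
#'   \code{sd}, \code{ci_lower}, \code{ci_upper}.
#' @slot nBootstrap,kFolds,seed protocol settings.
#' @slot config full pipeline configuration (list).
#' @exportClass BootstrapReport
setClass("BootstrapReport",
  representation(replicates = "data.frame", summary = "data.frame",
                 nBootstrap = "numeric", kFolds = "numeric",
                 seed = "numeric", config = "list"),
  prototype(config = list()))

setValidity("BootstrapReport", function(object) {
  r <- object@replicates
  need <- c("accuracy", "sensitivity", "specificity", "precision")
  if (!all(need %in% names(r)))
    return("replicates must contain the four metric columns")
  vals <- unlist(r[need])
  if (length(vals) && (any(vals < -1e-9) || any(vals > 100 + 1e-9)))
    return("metrics must lie in [0, 100]")
  if (nrow(r) != object@nBootstrap)
    return("replicate count must equal nBootstrap")
  TRUE
})
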