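# R surface of the LSTM feature extractor. The recurrence and BPTT live in
# src/lstm.cpp; everything stochastic (initial weights, shuffling) is drawn
# here under the configured seed, so training is deterministic end to end.

#' Training configuration for the LSTM
#'
#' Defaults follow the architecture's fixed hyperparameters: learning rate
#' 0.001, mini-batch size 4, L2 regularisation 0.0005, ADAM optimiser and
#' 30 training epochs over the dataset.
#'
#' @param learningRate step size (> 0).
#' @param miniBatch mini-batch size (>= 1).
#' @param l2 L2 penalty on weights, biases excluded (>= 0).
#' @param optimizer \code{"adam"} (beta1 0.9, beta2 0.999, eps 1e-8) or
#'   \code{"sgd_momentum"} (momentum 0.9).
#' @param epochs full passes over the training set (>= 1).
#' @param hiddenUnits LSTM hidden-state size H (default 256).
#' @param gradClip global gradient-norm clip; \code{NULL} or \code{<= 0}
#'   disables (default 1, for stability of 60-step backpropagation).
#' @param standardize z-score inputs per channel with training-set
#'   statistics (default on).
#' @param seed integer seed for initialisation and shuffling.
#' @return A validated list of class \code{TrainConfig}.
#' @export
#' @examples
#' trainConfig(hiddenUnits = 32)
trainConfig <- function(learningRate = 0.001, miniBatch = 4, l2 = 5e-4,
                        optimizer = c("adam", "sgd_momentum"), epochs = 30,
                        hiddenUnits = 256, gradClip = 1, standardize = TRUE,
                        seed = 1L) {
  optimizer <- match.arg(optimizer)
  stopifnot(learningRate > 0, miniBatch >= 1, l2 >= 0, epochs >= 1,
            hiddenUnits >= 1)
  structure(list(learningRate = learningRate,
                 miniBatch = as.integer(miniBatch), l2 = l2,
                 optimizer = optimizer, epochs = as.integer(epochs),
                 hiddenUnits = as.integer(hiddenUnits),
                 gradClip = if (is.null(gradClip)) 0 else gradClip,
                 standardize = isTRUE(standardize), seed = as.integer(seed)),
            class = "TrainConfig")
}

#' Initialise LSTM parameters
#'
#' Deterministic given \code{seed}: input and head weights are
#' Glorot-uniform, each recurrent gate block is a random orthogonal matrix,
#' biases are zero except the forget-gate bias which starts at 1 (keeping
#' the cell state open early in training).
#'
#' @param H hidden units (>= 1).
#' @param inputDim flattened per-step input size (canonically 63 x 100 =
#'   6300).
#' @param nClasses classes in the softmax head (default 3).
#' @param seed integer seed.
#' @return An \linkS4class{LSTMModel} (untrained).
#' @export
#' @examples
#' m <- initLSTM(8, 20, seed = 1)
#' hiddenUnits(m)
initLSTM <- function(H, inputDim, nClasses = 3, seed = 1L) {
  if (length(H) != 1 || H < 1) stop("H must be a positive integer")
  H <- as.integer(H); inputDim <- as.integer(inputDim)
  .withSeed(seed, {
    limW <- sqrt(6 / (inputDim + H))
    W <- matrix(stats::runif(4 * H * inputDim, -limW, limW), 4 * H, inputDim)
    R <- do.call(rbind, lapply(1:4, function(g)
      qr.Q(qr(matrix(stats::rnorm(H * H), H, H)))))
    b <- c(rep(1, H), rep(0, 3 * H))  # forget-gate bias = 1
    limY <- sqrt(6 / (H + nClasses))
    Wy <- matrix(stats::runif(nClasses * H, -limY, limY), nClasses, H)
    new("LSTMModel", W = W, R = R, b = b, Wy = Wy,
        by = rep(0, nClasses), classes = .classLevels[seq_len(nClasses)])
  })
}

.paramsList <- function(model)
  list(W = model@W, R = model@R, b = model@b, Wy = model@Wy, by = model@by)

# Flatten one StepSequence to a D x T matrix (column t = step t's
# channels-by-samples block, channel index varying fastest), with optional
# per-channel standardisation.
.seqMatrix <- function(seqc, center = NULL, scale = NULL) {
  d <- dim(seqc@data)
  M <- matrix(aperm(seqc@data, c(2, 3, 1)), d[2] * d[3], d[1])
  if (!is.null(center)) {
    M <- (M - rep(center, d[3])) / rep(scale, d[3])
  }
  M
}

.buildCube <- function(seqs, center = NULL, scale = NULL) {
  d <- dim(seqs[[1]]@data)
  X <- array(0, c(d[2] * d[3], d[1], length(seqs)))
  for (i in seq_along(seqs)) {
    di <- dim(seqs[[i]]@data)
    if (!all(di == d)) stop("all sequences must share the same shape")
    X[, , i] <- .seqMatrix(seqs[[i]], center, scale)
  }
  X
}

# Dataset container for the evaluation loops: one raw cube plus cached
# per-sequence channel sums, so per-fold standardisation statistics cost
# nothing and no standardised copy of the data is ever materialised.
.datasetCube <- function(seqs) {
  d <- dim(seqs[[1]]@data)
  n <- length(seqs)
  X <- .buildCube(seqs)
  chSum <- matrix(0, n, d[2])
  chSq <- matrix(0, n, d[2])
  for (i in seq_len(n)) {
    a <- aperm(seqs[[i]]@data, c(2, 1, 3))
    chSum[i, ] <- rowSums(matrix(a, d[2]))
    chSq[i, ] <- rowSums(matrix(a^2, d[2]))
  }
  list(X = X, labels = vapply(seqs, classLabel, character(1)),
       ids = vapply(seqs, recordingId, character(1)),
       chSum = chSum, chSq = chSq, steps = d[1], nchan = d[2],
       samples = d[3])
}

# per-channel standardisation statistics of the items `idx` (with
# multiplicity), identical to channelStats() on the corresponding list
.foldStats <- function(ds, idx) {
  n <- length(idx) * ds$steps * ds$samples
  center <- colSums(ds$chSum[idx, , drop = FALSE]) / n
  scale <- sqrt(pmax(colSums(ds$chSq[idx, , drop = FALSE]) / n - center^2,
                     0))
  scale[scale < 1e-12] <- 1
  list(center = center, scale = scale)
}

# expand per-channel stats to the flattened row layout (channel fastest)
.expandStats <- function(center, scale, samples) {
  if (!length(center)) list(center = numeric(0), scale = numeric(0))
  else list(center = rep(center, samples), scale = rep(scale, samples))
}

# training core on a dataset cube; idx selects the (possibly duplicated)
# training items
.trainOnCube <- function(ds, idx, config) {
  labs <- ds$labels[idx]
  if (!all(.classLevels %in% labs))
    stop("missing class(es): ",
         paste(setdiff(.classLevels, labs), collapse = ", "))
  y <- as.integer(factor(labs, levels = .classLevels)) - 1L
  norm <- if (config$standardize) .foldStats(ds, idx)
          else list(center = numeric(0), scale = numeric(0))
  ex <- .expandStats(norm$center, norm$scale, ds$samples)
  N <- length(idx)
  D <- ds$nchan * ds$samples
  res <- .withSeed(config$seed, {
    model <- initLSTM(config$hiddenUnits, D, nClasses = 3,
                      seed = sample.int(2^31 - 2, 1))
    order <- vapply(seq_len(config$epochs), function(e) sample.int(N),
                    integer(N))
    cfg <- list(learning_rate = config$learningRate, l2 = config$l2,
                grad_clip = config$gradClip, momentum = 0.9,
                beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8,
                epochs = config$epochs, mini_batch = config$miniBatch,
                optimizer = if (config$optimizer == "adam") "adam"
                            else "sgd")
    .lstmTrainCpp(.paramsList(model), ds$X, idx, y, cfg,
                  matrix(order, N, config$epochs), ex$center, ex$scale)
  })
  new("LSTMModel", W = res$W, R = res$R, b = as.numeric(res$b),
      Wy = res$Wy, by = as.numeric(res$by), classes = .classLevels,
      normCenter = norm$center, normScale = norm$scale,
      trace = as.numeric(res$trace), config = unclass(config))
}

# forward pass over selected items of a dataset cube
.forwardOnCube <- function(model, ds, idx, keep = FALSE) {
  ex <- .expandStats(model@normCenter, model@normScale, ds$samples)
  .lstmForwardCpp(.paramsList(model), ds$X, as.integer(idx), ex$center,
                  ex$scale, keep_states = keep)
}

#' Per-channel standardisation statistics of a training set
#'
#' @param seqs list of \linkS4class{StepSequence}s.
#' @return List with \code{center} and \code{scale} (one value per channel).
#' @export
channelStats <- function(seqs) {
  nchan <- dim(seqs[[1]]@data)[2]
  sums <- numeric(nchan); sq <- numeric(nchan); n <- 0
  for (s in seqs) {
    d <- dim(s@data)
    # channel index varies fastest along dim 2 of the data array
    sums <- sums + rowSums(matrix(aperm(s@data, c(2, 1, 3)), nchan))
    sq <- sq + rowSums(matrix(aperm(s@data, c(2, 1, 3))^2, nchan))
    n <- n + d[1] * d[3]
  }
  center <- sums / n
  scale <- sqrt(pmax(sq / n - center^2, 0))
  scale[scale < 1e-12] <- 1
  list(center = center, scale = scale)
}

.seqLabels <- function(seqs) {
  labs <- vapply(seqs, classLabel, character(1))
  if (anyNA(labs)) stop("all sequences must carry a class label")
  labs
}

#' Train the LSTM by backpropagation-through-time
#'
#' Runs \code{epochs} passes over shuffled mini-batches; gradients are
#' computed by full backpropagation through all time steps, parameters are
#' updated by ADAM or SGD-with-momentum, and the softmax cross-entropy loss
#' carries an L2 penalty on the weights. Deterministic given
#' \code{config$seed}.
#'
#' @param seqs list of labelled \linkS4class{StepSequence}s (at least one
#'   example of every class).
#' @param config a \code{\link{trainConfig}}.
#' @return A trained \linkS4class{LSTMModel}; the per-epoch mean training
#'   loss is available via \code{\link{lossTrace}}.
#' @export
trainLSTM <- function(seqs, config = trainConfig()) {
  if (!length(seqs)) stop("empty training set")
  .seqLabels(seqs)
  ds <- .datasetCube(seqs)
  .trainOnCube(ds, seq_along(seqs), config)
}

#' Run the LSTM forward over one sequence
#'
#' Unrolls the cell over all steps from zero initial hidden and cell
#' state: logistic forget/input/output gates, tanh candidate,
#' \eqn{c_t = f_t c_{t-1} + i_t s_t}, \eqn{h_t = o_t \tanh(c_t)}, and the
#' fully connected class scores on the final hidden state.
#'
#' @param model an \linkS4class{LSTMModel}.
#' @param seqc a \linkS4class{StepSequence} matching the model input size.
#' @return List with \code{states} (steps x H hidden states) and
#'   \code{scores} (one score per class).
#' @export
lstmForward <- function(model, seqc) {
  d <- dim(seqc@data)
  if (d[2] * d[3] != ncol(model@W))
    stop(sprintf("sequence input dim %d does not match model (%d)",
                 d[2] * d[3], ncol(model@W)))
  ex <- .expandStats(model@normCenter, model@normScale, d[3])
  M <- .seqMatrix(seqc)
  X <- array(M, c(nrow(M), ncol(M), 1))
  out <- .lstmForwardCpp(.paramsList(model), X, integer(0), ex$center,
                         ex$scale, keep_states = TRUE)
  states <- t(out$states[, 1, , drop = TRUE])  # T x H
  if (ncol(model@R) == 1) states <- matrix(states, ncol = 1)
  scores <- as.numeric(out$scores)
  names(scores) <- model@classes
  list(states = states, scores = scores)
}

#' Softmax cross-entropy loss with L2 penalty
#'
#' \eqn{-\log p_{label}} of the softmax over the class scores, plus
#' \eqn{l2 \cdot \frac{1}{2}\sum w^2} over the weight matrices (biases
#' excluded) when a model is supplied.
#'
#' @param scores numeric vector of class scores.
#' @param label true class: index (1-based) or class name.
#' @param model optional \linkS4class{LSTMModel} providing the weights for
#'   the penalty term.
#' @param l2 penalty coefficient.
#' @return The scalar loss.
#' @export
#' @examples
#' computeLoss(c(0, 0, 0), 1)  # log(3)
computeLoss <- function(scores, label, model = NULL, l2 = 0) {
  if (is.character(label)) label <- match(label, .classLevels)
  s <- scores - max(scores)
  p <- exp(s) / sum(exp(s))
  loss <- -log(p[label])
  if (l2 > 0 && !is.null(model))
    loss <- loss + 0.5 * l2 * (sum(model@W^2) + sum(model@R^2) +
                               sum(model@Wy^2))
  as.numeric(loss)
}

#' Extract LSTM features
#'
#' The feature vector of a recording is the final-step hidden state
#' \eqn{h_T} of the trained cell (length H, canonically 256); with
#' \code{pool = "mean"} the per-step average of hidden states is returned
#' instead.
#'
#' @param model a trained \linkS4class{LSTMModel}.
#' @param seqs a \linkS4class{StepSequence} or list thereof.
#' @param pool \code{"last"} (default) or \code{"mean"}.
#' @return Matrix of features, one row per sequence (row names are
#'   sequence ids, with a \code{"labels"} attribute).
#' @export
extractFeatures <- function(model, seqs, pool = c("last", "mean")) {
  pool <- match.arg(pool)
  if (is(seqs, "StepSequence")) seqs <- list(seqs)
  d <- dim(seqs[[1]]@data)
  if (d[2] * d[3] != ncol(model@W))
    stop(sprintf("sequence input dim %d does not match model (%d)",
                 d[2] * d[3], ncol(model@W)))
  ds <- .datasetCube(seqs)
  feats <- .featuresOnCube(model, ds, seq_along(seqs), pool)
  rownames(feats) <- ds$ids
  attr(feats, "labels") <- ds$labels
  feats
}

.featuresOnCube <- function(model, ds, idx, pool = "last") {
  out <- .forwardOnCube(model, ds, idx, keep = pool == "mean")
  feats <- if (pool == "last") t(out$h_last)
           else t(apply(out$states, c(1, 2), mean))
  if (nrow(feats) != length(idx)) feats <- matrix(feats, length(idx))
  feats
}

#' Predict classes with the LSTM's own softmax head
#'
#' @param model a trained \linkS4class{LSTMModel}.
#' @param seqs a \linkS4class{StepSequence} or list thereof.
#' @return Character vector of predicted class labels.
#' @export
predictSoftmax <- function(model, seqs) {
  if (is(seqs, "StepSequence")) seqs <- list(seqs)
  ds <- .datasetCube(seqs)
  out <- .forwardOnCube(model, ds, seq_along(seqs))
  model@classes[apply(out$scores, 2, which.max)]
}

#' Analytic BPTT gradients (and loss) for a labelled batch
#'
#' Exposed for gradient verification: returns the exact gradients the
#' training loop uses for one batch.
#'
#' @param model an \linkS4class{LSTMModel}.
#' @param seqs list of \linkS4class{StepSequence}s (the batch). No
#'   standardisation is applied.
#' @param labels class labels (names or 1-based indices).
#' @param l2 L2 coefficient.
#' @return List with \code{loss} and gradients \code{W}, \code{R},
#'   \code{b}, \code{Wy}, \code{by}.
#' @export
lstmGradients <- function(model, seqs, labels, l2 = 0) {
  if (is(seqs, "StepSequence")) seqs <- list(seqs)
  X <- .buildCube(seqs)
  if (is.character(labels)) labels <- match(labels, model@classes)
  .lstmLossGradCpp(.paramsList(model), X, as.integer(labels) - 1L, l2)
}
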