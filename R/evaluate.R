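# Assessment protocol: bootstrap resampling, per-replicate stratified
# 3-fold cross-validation of the full LSTM -> ECOC-SVM pipeline, and
# mean / SD / 95% percentile-CI summaries of the four metrics.

#' Evaluation configuration
#'
#' @param nBootstrap bootstrap replicates: 250 during design, 2000 for a
#'   final assessment (default 250).
#' @param kFolds cross-validation folds per replicate (default 3).
#' @param stratified draw bootstrap samples per class so every replicate
#'   keeps the class balance (default on; the unstratified variant can
#'   leave a class too small for 3-fold training splits).
#' @param head \code{"ecoc"} (ECOC-SVM on LSTM features, the proposed
#'   architecture) or \code{"softmax"} (the LSTM's own head, the ablation
#'   arm).
#' @param train a \code{\link{trainConfig}} for the per-fold LSTM.
#' @param svmCost,svmKernel binary SVM settings (defaults: cost 1, linear).
#' @param seed integer seed governing the whole evaluation.
#' @return A validated list of class \code{EvalConfig}.
#' @export
#' @examples
#' evalConfig(nBootstrap = 25, train = trainConfig(hiddenUnits = 32))
evalConfig <- function(nBootstrap = 250, kFolds = 3, stratified = TRUE,
                       head = c("ecoc", "softmax"), train = trainConfig(),
                       svmCost = 1, svmKernel = "linear", seed = 1L) {
  head <- match.arg(head)
  stopifnot(nBootstrap >= 1, kFolds >= 2)
  structure(list(nBootstrap = as.integer(nBootstrap),
                 kFolds = as.integer(kFolds),
                 stratified = isTRUE(stratified), head = head,
                 train = train, svmCost = svmCost, svmKernel = svmKernel,
                 seed = as.integer(seed)),
            class = "EvalConfig")
}

#' Draw one bootstrap sample
#'
#' Indices of a sample of the original size drawn with replacement from
#' the current RNG stream; with \code{stratified = TRUE} (default) each
#' class is resampled within itself, so class counts are preserved. Some
#' items appear repeatedly, others not at all.
#'
#' @param labels class label per dataset item.
#' @param stratified resample within classes (default) or from the pooled
#'   dataset.
#' @return Integer vector of indices, same length as \code{labels}.
#' @export
#' @examples
#' set.seed(1)
#' bootstrapSample(rep(c("healthy", "mild", "moderate"), each = 4))
bootstrapSample <- function(labels, stratified = TRUE) {
  n <- length(labels)
  if (n == 0) stop("empty dataset")
  if (!stratified) return(sample.int(n, n, replace = TRUE))
  idx <- unlist(lapply(unique(labels), function(cl) {
    who <- which(labels == cl)
    who[sample.int(length(who), length(who), replace = TRUE)]
  }), use.names = FALSE)
  as.integer(idx)
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy is the trace over the total; sensitivity, specificity and
#' precision are macro averages of the per-class one-vs-rest values
#' TP/(TP+FN), TN/(TN+FP) and TP/(TP+FP). A class never predicted
#' contributes precision 0 with a warning. All values in percent.
#'
#' @param confusion square count matrix, rows = true class, columns =
#'   predicted class.
#' @return Named numeric vector: \code{accuracy}, \code{sensitivity},
#'   \code{specificity}, \code{precision}.
#' @export
#' @examples
#' computeMetrics(diag(c(4, 4, 4)))
computeMetrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion))
    stop("confusion matrix must be square")
  if (any(confusion < 0)) stop("confusion counts must be non-negative")
  total <- sum(confusion)
  if (total == 0) stop("confusion matrix is all zero")
  K <- nrow(confusion)
  tp <- diag(confusion)
  fn <- rowSums(confusion) - tp
  fp <- colSums(confusion) - tp
  tn <- total - tp - fn - fp
  sens <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  spec <- ifelse(tn + fp > 0, tn / (tn + fp), 0)
  prec <- numeric(K)
  for (k in seq_len(K)) {
    if (tp[k] + fp[k] == 0) {
      warning("class ", k, " was never predicted; precision set to 0")
      prec[k] <- 0
    } else prec[k] <- tp[k] / (tp[k] + fp[k])
  }
  c(accuracy = 100 * sum(tp) / total,
    sensitivity = 100 * mean(sens),
    specificity = 100 * mean(spec),
    precision = 100 * mean(prec))
}

# Stratified fold assignment over the items of a (possibly resampled)
# dataset. All copies of the same original recording receive the same
# fold: letting duplicates straddle the train/test boundary lets a
# memorising learner score far above chance on label-free data, which
# breaks the protocol's chance-level calibration. On duplicate-free data
# this reduces to a plain stratified partition.
.foldAssignment <- function(ds, items, k, maxRetry = 10) {
  uni <- unique(items)
  uniLab <- ds$labels[uni]
  for (r in seq_len(maxRetry)) {
    foldU <- integer(length(uni))
    for (cl in unique(uniLab)) {
      who <- which(uniLab == cl)
      f <- (seq_along(who) - 1L) %% k + 1L
      foldU[who] <- f[sample.int(length(who))]
    }
    fold <- foldU[match(items, uni)]
    ok <- all(vapply(seq_len(k), function(f)
      all(.classLevels %in% ds$labels[items[fold != f]]), logical(1)))
    if (ok) return(fold)
  }
  stop("could not build ", k, "-fold splits with every class in every ",
       "training set")
}

#' Cross-validate the pipeline on one (bootstrap) sample
#'
#' Stratified k-fold partition; per fold an LSTM is trained on the
#' training folds (with its own standardisation statistics), features are
#' extracted for both sides, the classification head is fitted on the
#' training features and the held-out items are predicted. All copies of
#' a duplicated bootstrap item share one fold, so no recording sits on
#' both sides of a train/test boundary (see the methods vignette for why
#' the alternative inflates accuracy on label-free data). Fold assignment
#' and per-fold training seeds are drawn from the current RNG stream.
#'
#' @param seqs list of labelled \linkS4class{StepSequence}s.
#' @param config an \code{\link{evalConfig}} (its \code{nBootstrap} is
#'   ignored here).
#' @return The pooled confusion matrix over folds (rows = true class).
#' @export
crossValidate <- function(seqs, config = evalConfig()) {
  .seqLabels(seqs)
  .crossValidateCube(.datasetCube(seqs), seq_along(seqs), config)
}

# cube-based core: `items` are (possibly duplicated) indices into ds
.crossValidateCube <- function(ds, items, config) {
  labels <- ds$labels[items]
  k <- config$kFolds
  fold <- .foldAssignment(ds, items, k)
  conf <- matrix(0L, 3, 3, dimnames = list(.classLevels, .classLevels))
  foldSeeds <- sample.int(2^31 - 2, k)
  for (f in seq_len(k)) {
    tr <- which(fold != f)
    te <- which(fold == f)
    if (!length(te)) next  # small resamples can leave a fold empty
    tc <- config$train
    tc$seed <- foldSeeds[f]
    model <- .trainOnCube(ds, items[tr], tc)
    if (config$head == "ecoc") {
      feats <- .featuresOnCube(model, ds, items[c(tr, te)])
      ftr <- feats[seq_along(tr), , drop = FALSE]
      fte <- feats[length(tr) + seq_along(te), , drop = FALSE]
      ecoc <- trainEcoc(ftr, labels[tr], cost = config$svmCost,
                        kernel = config$svmKernel)
      pred <- predictEcoc(ecoc, fte)
    } else {
      out <- .forwardOnCube(model, ds, items[te])
      pred <- model@classes[apply(out$scores, 2, which.max)]
    }
    for (i in seq_along(te))
      conf[labels[te[i]], pred[i]] <- conf[labels[te[i]], pred[i]] + 1L
  }
  conf
}

#' Bootstrap evaluation of the full architecture
#'
#' For each replicate: draw a bootstrap sample of the original size,
#' run stratified k-fold cross-validation of the LSTM -> head pipeline on
#' it, and record accuracy, sensitivity, specificity and precision from
#' the pooled confusion matrix. Metrics are summarised by mean, standard
#' deviation and the 95\% percentile confidence interval (2.5th / 97.5th
#' percentiles). Deterministic given \code{config$seed}; a failing
#' replicate is retried once with a derived seed.
#'
#' @param seqs list of labelled \linkS4class{StepSequence}s.
#' @param config an \code{\link{evalConfig}}.
#' @return A \linkS4class{BootstrapReport}.
#' @export
runBootstrapEvaluation <- function(seqs, config = evalConfig()) {
  labels <- .seqLabels(seqs)
  ds <- .datasetCube(seqs)
  repSeeds <- .withSeed(config$seed,
                        sample.int(2^31 - 2, config$nBootstrap))
  rows <- vector("list", config$nBootstrap)
  for (b in seq_len(config$nBootstrap)) {
    runOne <- function(sd) .withSeed(sd, {
      idx <- bootstrapSample(labels, config$stratified)
      computeMetrics(.crossValidateCube(ds, idx, config))
    })
    m <- tryCatch(runOne(repSeeds[b]), error = function(e) {
      warning("replicate ", b, " failed (", conditionMessage(e),
              "); retrying with a derived seed")
      runOne((repSeeds[b] + 1L) %% (2^31 - 2) + 1L)
    })
    rows[[b]] <- data.frame(replicate = b, t(m))
  }
  reps <- do.call(rbind, rows)
  metrics <- c("accuracy", "sensitivity", "specificity", "precision")
  summ <- do.call(rbind, lapply(metrics, function(m) {
    v <- reps[[m]]
    ci <- stats::quantile(v, c(0.025, 0.975), names = FALSE)
    data.frame(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0,
               ci_lower = ci[1], ci_upper = ci[2], row.names = m)
  }))
  new("BootstrapReport", replicates = reps, summary = summ,
      nBootstrap = config$nBootstrap, kFolds = config$kFolds,
      seed = config$seed, config = unclass(config))
}
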