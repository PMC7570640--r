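# End-to-end pipeline: simulate (or load) -> preprocess -> bootstrap
# evaluation, with one global seed deterministically split across stages.

#' Pipeline configuration
#'
#' Bundles the per-stage configurations and a single global seed from
#' which every stage's seed is derived deterministically. Accepts either
#' explicit sub-configurations or a YAML file with sections
#' \code{simulation}, \code{preprocessing}, \code{training}, \code{svm}
#' and \code{evaluation} (each holding the corresponding constructor's
#' arguments) plus a top-level \code{seed}.
#'
#' @param simulation \code{\link{simConfig}} arguments (list) or a ready
#'   config.
#' @param preprocessing list with any of \code{raw}, \code{antiAlias},
#'   \code{autoArtifacts}.
#' @param training \code{\link{trainConfig}} arguments (list) or config.
#' @param svm list with \code{cost} and/or \code{kernel}.
#' @param evaluation \code{\link{evalConfig}} arguments (list) or config.
#' @param seed global seed.
#' @return A list of class \code{PipelineConfig}.
#' @export
#' @examples
#' cfg <- pipelineConfig(training = list(hiddenUnits = 32),
#'                       evaluation = list(nBootstrap = 5))
pipelineConfig <- function(simulation = list(), preprocessing = list(),
                           training = list(), svm = list(),
                           evaluation = list(), seed = 1L) {
  seed <- as.integer(seed)
  sub <- .withSeed(seed, sample.int(2^31 - 2, 3))
  sim <- if (inherits(simulation, "SimulationConfig")) simulation
         else do.call(simConfig, utils::modifyList(list(seed = sub[1]),
                                                   simulation))
  train <- if (inherits(training, "TrainConfig")) training
           else do.call(trainConfig, training)
  evalArgs <- utils::modifyList(
    list(seed = sub[2], train = train,
         svmCost = if (is.null(svm$cost)) 1 else svm$cost,
         svmKernel = if (is.null(svm$kernel)) "linear" else svm$kernel),
    if (inherits(evaluation, "EvalConfig")) unclass(evaluation)
    else evaluation)
  evalArgs$train <- train
  ev <- do.call(evalConfig, evalArgs)
  pp <- utils::modifyList(list(raw = FALSE, antiAlias = FALSE,
                               autoArtifacts = TRUE), preprocessing)
  structure(list(simulation = sim, preprocessing = pp, evaluation = ev,
                 seed = seed), class = "PipelineConfig")
}

#' @rdname pipelineConfig
#' @param path YAML file with the sections described above.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipelineConfig, y[intersect(names(y),
    c("simulation", "preprocessing", "training", "svm", "evaluation",
      "seed"))])
}

#' Run the full pipeline
#'
#' Simulates the configured dataset (streaming recordings one at a time
#' to bound memory), preprocesses each recording into its step sequence,
#' runs the bootstrap evaluation, and optionally writes the replicate
#' table, summary JSON and a provenance log of every seed and setting.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param recordings optional list of \linkS4class{RawRecording}s to use
#'   instead of simulating.
#' @param outDir optional output directory.
#' @return A \linkS4class{BootstrapReport}.
#' @export
runPipeline <- function(config = pipelineConfig(), recordings = NULL,
                        outDir = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  pp <- config$preprocessing
  prep <- function(rec) preprocessRecording(
    rec, autoArtifacts = pp$autoArtifacts, raw = pp$raw,
    antiAlias = pp$antiAlias)
  if (is.null(recordings)) {
    plan <- datasetPlan(config$simulation)
    seqs <- lapply(seq_len(nrow(plan)), function(i)
      prep(simulateRecording(plan$label[i], config$simulation,
                             seed = plan$seed[i], id = plan$id[i])))
  } else {
    seqs <- lapply(recordings, prep)
  }
  report <- runBootstrapEvaluation(seqs, config$evaluation)
  if (!is.null(outDir)) {
    writeReport(report, outDir)
    jsonlite::write_json(
      list(seed = config$seed, simulation = config$simulation[
             setdiff(names(config$simulation), "bandPowers")],
           bands = config$simulation$bandPowers,
           preprocessing = pp,
           evaluation = unclass(config$evaluation)),
      file.path(outDir, "provenance.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "rows", force = TRUE)
  }
  report
}
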