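# Hill-climbing hyperparameter sweep: one axis at a time, fixing each
# axis at its best-accuracy value before moving to the next.

#' Hill-climbing hyperparameter sweep
#'
#' Evaluates one axis at a time in the fixed order learning rate ->
#' mini-batch size -> hidden units -> optimizer, running a bootstrap
#' evaluation for every grid value and fixing each axis at its
#' best-mean-accuracy value before sweeping the next. The study's grids
#' were learning rates \{0.1, 0.01, 0.001, 0.0001\}, batch sizes
#' \{1, 2, 4, 8, 16, 32, 64\}, hidden units \{8, 16, 32, 64, 128, 256\}
#' and optimizers \{sgd_momentum, adam\}; any subset may be supplied.
#'
#' @param seqs list of labelled \linkS4class{StepSequence}s.
#' @param grid named list with any of \code{learningRate},
#'   \code{miniBatch}, \code{hiddenUnits}, \code{optimizer}; axes are
#'   swept in that order regardless of list order.
#' @param config base \code{\link{evalConfig}}; its \code{train} settings
#'   provide the values of axes not yet swept.
#' @return List with \code{table} (one row per evaluated setting: axis,
#'   value, metric means and SDs, and whether it was selected),
#'   \code{best} (the final \code{\link{trainConfig}}) and \code{reports}
#'   (every \linkS4class{BootstrapReport}, named \code{axis=value}).
#' @export
sweepHyperparameters <- function(seqs, grid, config = evalConfig()) {
  axes <- c("learningRate", "miniBatch", "hiddenUnits", "optimizer")
  grid <- grid[intersect(axes, names(grid))]
  if (!length(grid)) stop("grid must name at least one axis")
  current <- config$train
  rows <- list()
  reports <- list()
  for (ax in names(grid)) {
    vals <- grid[[ax]]
    accs <- numeric(length(vals))
    axRows <- vector("list", length(vals))
    for (i in seq_along(vals)) {
      tc <- current
      tc[[ax]] <- if (ax == "optimizer") as.character(vals[i])
                  else as.numeric(vals[i])
      if (ax %in% c("miniBatch", "hiddenUnits"))
        tc[[ax]] <- as.integer(tc[[ax]])
      cfg <- config
      cfg$train <- tc
      rep <- runBootstrapEvaluation(seqs, cfg)
      s <- metricSummary(rep)
      accs[i] <- s["accuracy", "mean"]
      axRows[[i]] <- data.frame(
        axis = ax, value = as.character(vals[i]),
        accuracy = s["accuracy", "mean"], accuracy_sd = s["accuracy", "sd"],
        sensitivity = s["sensitivity", "mean"],
        specificity = s["specificity", "mean"],
        precision = s["precision", "mean"], selected = FALSE)
      reports[[paste0(ax, "=", vals[i])]] <- rep
    }
    best <- which.max(accs)
    axRows[[best]]$selected <- TRUE
    current[[ax]] <- if (ax == "optimizer") as.character(vals[best])
                     else if (ax %in% c("miniBatch", "hiddenUnits"))
                       as.integer(vals[best])
                     else as.numeric(vals[best])
    rows <- c(rows, axRows)
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  list(table = table, best = current, reports = reports)
}
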