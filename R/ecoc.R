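# One-vs-one error-correcting output code SVM over LSTM features.

#' The one-vs-one coding design of the three-class architecture
#'
#' Returns the exhaustive (one-vs-one) coding matrix: learner 1 separates
#' healthy (+1) from mild (-1), learner 2 healthy (+1) from moderate (-1),
#' learner 3 mild (+1) from moderate (-1); 0 entries mean the class is
#' omitted from that learner's training set.
#'
#' @return A \linkS4class{CodingDesign} with rows (healthy, mild,
#'   moderate) and columns (SVM1, SVM2, SVM3).
#' @export
#' @examples
#' designMatrix(defaultDesign())
defaultDesign <- function() {
  M <- rbind(healthy  = c(1, 1, 0),
             mild     = c(-1, 0, 1),
             moderate = c(0, -1, -1))
  colnames(M) <- paste0("SVM", 1:3)
  codingDesign(M)
}

#' Train an ECOC-SVM on feature vectors
#'
#' Features are z-standardised with training statistics, then one binary
#' margin classifier is fitted per design column: examples of classes
#' coded +1 form the positive set, -1 the negative set, and 0-coded
#' classes are excluded. The binary learners are linear support vector
#' machines (cost \code{C}), the standard choice for a few dozen examples
#' in a 256-dimensional feature space.
#'
#' @param features numeric matrix, one row per example (e.g. from
#'   \code{\link{extractFeatures}}).
#' @param labels class labels, one per row; defaults to the matrix's
#'   \code{"labels"} attribute.
#' @param design a \linkS4class{CodingDesign} (default
#'   \code{\link{defaultDesign}}).
#' @param cost SVM cost parameter (default 1).
#' @param kernel SVM kernel (default \code{"linear"}).
#' @return An \linkS4class{EcocModel}.
#' @export
trainEcoc <- function(features, labels = attr(features, "labels"),
                      design = defaultDesign(), cost = 1,
                      kernel = "linear") {
  features <- as.matrix(features)
  if (is.null(labels)) stop("labels are required")
  labels <- as.character(labels)
  M <- designMatrix(design)
  classes <- rownames(M)
  if (!all(labels %in% classes))
    stop("labels outside the design's classes: ",
         paste(setdiff(labels, classes), collapse = ", "))

  center <- colMeans(features)
  scale <- apply(features, 2, stats::sd)
  scale[!is.finite(scale) | scale < 1e-12] <- 1
  Z <- sweep(sweep(features, 2, center, "-"), 2, scale, "/")

  learners <- vector("list", ncol(M))
  for (j in seq_len(ncol(M))) {
    pos <- classes[M[, j] == 1]
    neg <- classes[M[, j] == -1]
    sel <- labels %in% c(pos, neg)
    if (!any(labels %in% pos) || !any(labels %in% neg))
      stop(sprintf("column %s has an empty positive or negative set",
                   colnames(M)[j]))
    yb <- factor(ifelse(labels[sel] %in% pos, 1, -1), levels = c(-1, 1))
    learners[[j]] <- e1071::svm(Z[sel, , drop = FALSE], yb, kernel = kernel,
                                cost = cost, scale = FALSE)
  }
  new("EcocModel", design = design, learners = learners, center = center,
      scale = scale, classes = classes)
}

#' Hamming-decode a binary prediction vector
#'
#' Compares a vector of \{-1, +1\} learner outputs against every class
#' codeword: the distance to a row counts the positions whose entry is
#' nonzero and whose sign disagrees (0-coded positions are ignored). The
#' class at minimal distance wins; ties break towards the earlier row
#' (healthy before mild before moderate).
#'
#' @param pred numeric vector of learner outputs in \{-1, +1\}, one per
#'   design column.
#' @param design a \linkS4class{CodingDesign}.
#' @return The decoded class label (character).
#' @export
#' @examples
#' hammingDecode(c(1, 1, -1), defaultDesign())
hammingDecode <- function(pred, design = defaultDesign()) {
  M <- designMatrix(design)
  if (length(pred) != ncol(M))
    stop("prediction length must equal the number of learners")
  if (!all(pred %in% c(-1, 1)))
    stop("prediction entries must be -1 or +1")
  dist <- apply(M, 1, function(row) sum(row != 0 & row != pred))
  rownames(M)[which.min(dist)]  # which.min takes the first minimum: row-order tie-break
}

#' Predict classes with a trained ECOC-SVM
#'
#' Standardises the features with the training statistics, takes each
#' binary learner's sign, and Hamming-decodes the resulting code vector.
#'
#' @param object an \linkS4class{EcocModel}.
#' @param features numeric matrix (or single feature vector) matching the
#'   training dimension.
#' @return Character vector of predicted class labels, one per row.
#' @export
predictEcoc <- function(object, features) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  features <- as.matrix(features)
  if (ncol(features) != length(object@center))
    stop(sprintf("feature dimension %d does not match training dimension %d",
                 ncol(features), length(object@center)))
  Z <- sweep(sweep(features, 2, object@center, "-"), 2, object@scale, "/")
  codes <- vapply(object@learners, function(l)
    as.numeric(as.character(stats::predict(l, Z))), numeric(nrow(Z)))
  codes <- matrix(codes, nrow = nrow(Z))
  vapply(seq_len(nrow(Z)), function(i)
    hammingDecode(codes[i, ], object@design), character(1))
}

#' @describeIn predictEcoc Standard \code{predict} method.
#' @param ... unused.
#' @export
setMethod("predict", "EcocModel", function(object, features, ...)
  predictEcoc(object, features))
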