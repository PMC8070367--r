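#' Intermediate-integration feature vector
#'
#' Concatenates the text document vector (first) and the reduced geometric
#' vector (second): 200 + 50 = 250 dimensions under the defaults. The order
#' is fixed so serialized models stay valid.
#'
#' @param doc numeric document vector (or matrix, rows = records).
#' @param reduced numeric reduced geometric vector (or matching matrix).
#' @return Concatenated vector (or matrix).
#' @export
buildIntermediateFeature <- function(doc, reduced) {
  .assertFinite(doc, "document vector")
  .assertFinite(reduced, "reduced vector")
  if (is.null(dim(doc)) && is.null(dim(reduced))) return(c(doc, reduced))
  doc <- as.matrix(doc)
  reduced <- as.matrix(reduced)
  if (nrow(doc) != nrow(reduced)) stop("row mismatch between views")
  cbind(doc, reduced)
}

#' Train the randomized-tree ensemble classifier
#'
#' A random forest (100 trees, sqrt-feature subsampling, unlimited depth)
#' with probability output, deterministic given `seed`. Class-probability
#' columns always follow the full label-set order; classes absent from
#' training get probability 0.
#'
#' @param features numeric matrix, rows = records.
#' @param labels class name per record; >= 2 distinct values.
#' @param labelSet a [LabelSet-class].
#' @param numTrees number of trees (default 100).
#' @param seed integer seed.
#' @return An [EnsembleClassifier-class].
#' @export
trainClassifier <- function(features, labels, labelSet, numTrees = 100L,
                            seed = 1L) {
  cn <- classNames(labelSet)
  if (length(unique(labels)) < 2) stop("degenerate task: single-class input")
  if (!all(labels %in% cn)) stop("labels outside the label set")
  df <- as.data.frame(features)
  colnames(df) <- paste0("f", seq_len(ncol(df)))
  y <- droplevels(factor(labels, levels = cn))
  fit <- ranger::ranger(x = df, y = y, probability = TRUE,
                        num.trees = numTrees, seed = seed, num.threads = 1L)
  new("EnsembleClassifier", fit = fit, classNames = cn,
      config = list(numTrees = numTrees, seed = seed))
}

#' @describeIn trainClassifier class-probability predictions in label-set
#'   order (rows sum to 1).
#' @param classifier an [EnsembleClassifier-class].
#' @export
predictClassifierProba <- function(classifier, features) {
  df <- as.data.frame(features)
  colnames(df) <- paste0("f", seq_len(ncol(df)))
  p <- predict(classifier@fit, data = df, num.threads = 1L)$predictions
  out <- matrix(0, nrow(df), length(classifier@classNames),
                dimnames = list(NULL, classifier@classNames))
  out[, colnames(p)] <- p
  out
}

.checkViews <- function(viewProbs) {
  if (!length(viewProbs)) stop("need at least one view")
  viewProbs <- lapply(viewProbs, function(v) if (is.null(dim(v)))
    matrix(v, 1, dimnames = list(NULL, names(v))) else as.matrix(v))
  dims <- vapply(viewProbs, dim, integer(2))
  if (length(unique(dims[2, ])) != 1)
    stop("views disagree in class count")
  if (length(unique(dims[1, ])) != 1)
    stop("views disagree in record count")
  cn <- lapply(viewProbs, colnames)
  cn <- cn[!vapply(cn, is.null, logical(1))]
  if (length(cn) > 1 && !all(vapply(cn[-1], identical, logical(1), cn[[1]])))
    stop("views disagree in class order")
  viewProbs
}

#' Late integration: average (AVG) fusion
#'
#' Element-wise mean of the per-view probability vectors; the result is a
#' valid distribution. Optional per-view weights (normalized internally)
#' allow a weighted average for experimentation; the default is the plain
#' equal-weight mean.
#'
#' @param viewProbs list of probability vectors (or matrices with one row
#'   per record), same class order.
#' @param weights optional nonnegative per-view weights.
#' @return Fused probabilities, same shape as one input view.
#' @export
fuseAvg <- function(viewProbs, weights = NULL) {
  if (!length(viewProbs)) stop("need at least one view")
  single <- is.null(dim(viewProbs[[1]]))
  vp <- .checkViews(viewProbs)
  if (is.null(weights)) weights <- rep(1, length(vp))
  if (length(weights) != length(vp) || any(weights < 0) ||
      sum(weights) <= 0)
    stop("weights must be nonnegative, one per view, with positive sum")
  w <- weights / sum(weights)
  out <- Reduce(`+`, Map(`*`, vp, w))
  if (single) out[1, ] else out
}

#' Late integration: maximum (MAX) fusion
#'
#' Takes the per-class maximum over views. The fused scores are kept as raw
#' maxima (renormalization cannot change the argmax); the predicted class
#' is the argmax, ties broken by class order.
#'
#' @inheritParams fuseAvg
#' @return list with `scores` (same shape as one view) and `class`
#'   (character, one per record).
#' @export
fuseMax <- function(viewProbs) {
  if (!length(viewProbs)) stop("need at least one view")
  single <- is.null(dim(viewProbs[[1]]))
  vp <- .checkViews(viewProbs)
  out <- Reduce(pmax, vp)
  cls <- colnames(out)[apply(out, 1, which.max)]
  list(scores = if (single) out[1, ] else out, class = cls)
}

#' Final class from two fused views
#'
#' Argmax of the AVG- or MAX-fused text and image probability vectors; ties
#' broken by class order.
#'
#' @param textProbs,imageProbs probability vectors/matrices over the same
#'   label set.
#' @param method `"avg"` or `"max"`.
#' @return Character vector of predicted class names.
#' @export
predictLate <- function(textProbs, imageProbs, method = c("avg", "max")) {
  method <- match.arg(method)
  vp <- .checkViews(list(textProbs, imageProbs))
  fused <- if (method == "avg") Reduce(`+`, vp) / 2 else Reduce(pmax, vp)
  colnames(fused)[apply(fused, 1, which.max)]
}
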