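#' Confusion matrix over a fixed label set
#'
#' @param truth,pred equal-length character vectors of class names; every
#'   value must belong to the label set.
#' @param labelSet a [LabelSet-class] fixing row/column order.
#' @return |L| x |L| integer matrix, rows = truth, columns = prediction.
#' @export
confusionCounts <- function(truth, pred, labelSet) {
  if (length(truth) != length(pred) || length(truth) < 1)
    stop("truth and pred must have equal positive length")
  cn <- classNames(labelSet)
  bad <- setdiff(unique(c(truth, pred)), cn)
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  m <- table(factor(truth, levels = cn), factor(pred, levels = cn))
  matrix(as.integer(m), nrow = length(cn), dimnames = list(cn, cn))
}

#' Macro-averaged metrics from a confusion matrix
#'
#' Per class c: precision = TP/(TP+FP), recall = TP/(TP+FN), F1 their
#' harmonic mean; ratios with zero denominator count as 0. The macro
#' averages weight each class equally, running over the N classes present
#' in truth or prediction (union-label convention) rather than the full
#' label set, so classes absent from an evaluation do not dilute the
#' average. Accuracy is the multiclass trace/total.
#'
#' @param cm confusion matrix from [confusionCounts()].
#' @return An [EvaluationReport-class].
#' @export
computeMetrics <- function(cm) {
  total <- sum(cm)
  if (total < 1) stop("empty confusion matrix")
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- total - tp - fp - fn
  prec <- ifelse(tp + fp == 0, 0, tp / (tp + fp))
  rec <- ifelse(tp + fn == 0, 0, tp / (tp + fn))
  f1 <- ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec))
  present <- rowSums(cm) > 0 | colSums(cm) > 0
  perClass <- data.frame(class = rownames(cm), tp = as.integer(tp),
    fp = as.integer(fp), fn = as.integer(fn), tn = as.integer(tn),
    precision = prec, recall = rec, f1 = f1, present = present,
    row.names = NULL)
  new("EvaluationReport", confusion = cm, perClass = perClass,
      macroPrecision = mean(prec[present]), macroRecall = mean(rec[present]),
      macroF1 = mean(f1[present]), accuracy = sum(tp) / total,
      nEvaluated = as.integer(sum(present)))
}

#' Majority-label baseline classifier
#'
#' Always predicts the most frequent training label; ties are broken by
#' label-set order. On an imbalanced structure-set cohort this predicts
#' "other" and anchors the bottom of the metric range.
#'
#' @param trainLabels character vector of training labels (>= 1).
#' @param labelSet a [LabelSet-class].
#' @return An [MLBClassifier-class]; call [predict()] on it with `n` (count)
#'   or a vector whose length sets the number of predictions.
#' @export
majorityLabelBaseline <- function(trainLabels, labelSet) {
  if (length(trainLabels) < 1) stop("need at least one training label")
  cn <- classNames(labelSet)
  counts <- table(factor(trainLabels, levels = cn))
  new("MLBClassifier", label = cn[which.max(counts)], classNames = cn)
}

#' @describeIn majorityLabelBaseline constant predictions.
#' @param object an [MLBClassifier-class].
#' @param newdata vector (its length is used) or a count.
#' @param ... ignored.
#' @export
setMethod("predict", "MLBClassifier", function(object, newdata, ...) {
  n <- if (length(newdata) == 1 && is.numeric(newdata)) newdata
       else length(newdata)
  rep(object@label, n)
})

#' Stratified k-fold split plan
#'
#' Folds are stratified by label: within each class, shuffled records are
#' dealt round-robin, so per-fold class counts differ by at most 1 from
#' perfect proportionality. Deterministic given `seed`.
#'
#' @param labels character vector of record labels.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return A [SplitPlan-class] with `k` splits of `train`/`validation`
#'   index vectors.
#' @export
stratifiedKFold <- function(labels, k = 5L, seed = 1L) {
  n <- length(labels)
  k <- as.integer(k)
  if (k < 2) stop("k must be >= 2")
  if (k > n) stop("k exceeds the number of records")
  fold <- integer(n)
  withr::with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- (seq_along(idx) - 1L) %% k + 1L
    }
  })
  splits <- lapply(seq_len(k), function(f)
    list(train = which(fold != f), validation = which(fold == f)))
  new("SplitPlan", scheme = "kfold5", splits = splits)
}

#' Leave-one-center-out split plan
#'
#' One split per center: that center's records form the validation fold and
#' all other centers' records the training set, testing cross-site
#' generalization.
#'
#' @param centers character vector of center ids, one per record.
#' @return A [SplitPlan-class].
#' @export
centerCrossValidation <- function(centers) {
  uc <- unique(centers)
  if (length(uc) < 2) stop("need at least 2 centers")
  splits <- lapply(uc, function(ct)
    list(train = which(centers != ct), validation = which(centers == ct)))
  names(splits) <- uc
  new("SplitPlan", scheme = "center_loo", splits = splits)
}

#' Center-level holdout split plan
#'
#' Randomly assigns whole centers to the test side, so no patient (or
#' center) straddles train and test. Deterministic given `seed`.
#'
#' @param centers character vector of center ids, one per record.
#' @param nTestCenters number of centers held out for testing.
#' @param seed integer seed.
#' @return A [SplitPlan-class] with one `train`/`test` split; the held-out
#'   center ids are attached as the split's `testCenters`.
#' @export
centerHoldout <- function(centers, nTestCenters, seed = 1L) {
  uc <- unique(centers)
  if (nTestCenters < 1 || nTestCenters >= length(uc))
    stop("nTestCenters must be in [1, number of centers - 1]")
  testCenters <- withr::with_seed(seed, sample(uc, nTestCenters))
  split <- list(train = which(!centers %in% testCenters),
                test = which(centers %in% testCenters),
                testCenters = testCenters)
  new("SplitPlan", scheme = "center_holdout", splits = list(split))
}

#' Round metrics for display
#'
#' Half-away-from-zero rounding to `digits` decimals, the convention used
#' for reported tables.
#'
#' @param x numeric.
#' @param digits decimals (default 3).
#' @export
displayRound <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Serialize an evaluation report
#'
#' JSON carries full precision; CSV applies display rounding.
#'
#' @param report an [EvaluationReport-class].
#' @param jsonPath,csvPath,confusionCsvPath output files (NULL to skip).
#' @return Invisibly, the report as a list.
#' @export
writeEvaluationReport <- function(report, jsonPath = NULL, csvPath = NULL,
                                  confusionCsvPath = NULL) {
  lst <- list(
    macro_precision = report@macroPrecision,
    macro_recall = report@macroRecall,
    macro_f1 = report@macroF1,
    accuracy = report@accuracy,
    n_evaluated_labels = report@nEvaluated,
    per_class = report@perClass)
  if (!is.null(jsonPath))
    jsonlite::write_json(lst, jsonPath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (!is.null(csvPath)) {
    pc <- report@perClass
    num <- vapply(pc, is.numeric, logical(1)) &
      !vapply(pc, is.integer, logical(1))
    pc[num] <- lapply(pc[num], displayRound)
    write.csv(pc, csvPath, row.names = FALSE)
  }
  if (!is.null(confusionCsvPath))
    write.csv(as.data.frame(report@confusion), confusionCsvPath)
  invisible(lst)
}
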