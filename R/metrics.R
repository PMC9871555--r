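#' Multi-class validation metrics
#'
#' Computes accuracy, macro-averaged precision and recall, and
#' macro-averaged one-vs-rest AUC for a 14-class PMI prediction. Macro
#' averages are unweighted over classes (the study design is
#' class-balanced); a class with no predicted positives contributes
#' precision 0.
#'
#' @param prob Matrix of class probabilities (rows = samples, columns
#'   named by class level), or NULL if the model has no probability
#'   output (AUC is then NA).
#' @param truth Factor of true labels; its levels define the class set.
#' @param predicted Optional factor of predicted labels; defaults to the
#'   probability argmax with ties broken toward the earlier PMI class.
#' @return Named numeric vector: accuracy, precision, recall, auc.
#' @export
evaluate_predictions <- function(prob, truth, predicted = NULL) {
  truth <- as.factor(truth)
  lev <- levels(truth)
  if (is.null(predicted)) {
    stopifnot(!is.null(prob))
    predicted <- predict_classes(prob, lev)
  }
  predicted <- factor(predicted, levels = lev)
  cm <- table(truth = truth, predicted = predicted)
  acc <- sum(diag(cm)) / sum(cm)
  prec_k <- diag(cm) / colSums(cm)
  prec_k[colSums(cm) == 0] <- 0          # no predicted positives
  present <- rowSums(cm) > 0
  rec_k <- diag(cm)[present] / rowSums(cm)[present]
  prec <- mean(prec_k[present])
  rec <- mean(rec_k)
  auc <- if (is.null(prob)) NA_real_ else macro_auc(prob, truth)
  c(accuracy = acc, precision = prec, recall = rec, auc = auc)
}

#' Argmax class prediction with earlier-PMI tie-breaking
#'
#' @param prob Probability matrix with columns named by class level.
#' @param levels Class levels in day order (defaults to column order).
#' @return Factor of predicted classes; probability ties go to the
#'   earlier (smaller) PMI day, each occurrence logged via `message`.
#' @export
predict_classes <- function(prob, levels = colnames(prob)) {
  prob <- prob[, levels, drop = FALSE]
  idx <- apply(prob, 1, function(p) {
    w <- which(p >= max(p) - 1e-12)
    w[1]  # columns are in day order: first = earlier PMI
  })
  n_tie <- sum(apply(prob, 1, function(p) sum(p >= max(p) - 1e-12) > 1))
  if (n_tie > 0) message(n_tie, " argmax tie(s) broken toward the earlier PMI class")
  factor(levels[idx], levels = levels)
}

#' @keywords internal
macro_auc <- function(prob, truth) {
  lev <- levels(truth)
  prob <- prob[, lev, drop = FALSE]
  aucs <- vapply(lev, function(cl) {
    y <- as.integer(truth == cl)
    if (length(unique(y)) < 2) return(NA_real_)
    as.numeric(pROC::auc(pROC::roc(y, prob[, cl], quiet = TRUE,
                                   direction = "<", levels = c(0, 1))))
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

#' Confusion matrix report
#'
#' @param predicted,truth Factors over the PMI day classes (day order).
#' @return list: `matrix` (truth x predicted, day order), `per_class`
#'   (row sums = samples per true class), `misjudged` (total - trace).
#' @export
report_confusion <- function(predicted, truth) {
  truth <- as.factor(truth)
  lev <- levels(truth)
  if (!all(as.character(predicted) %in% lev)) {
    stop("unknown class label in predictions")
  }
  predicted <- factor(predicted, levels = lev)
  cm <- table(truth = truth, predicted = predicted)
  list(matrix = cm,
       per_class = rowSums(cm),
       misjudged = sum(cm) - sum(diag(cm)))
}
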