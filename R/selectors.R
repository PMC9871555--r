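#' Stratified cross-validation folds
#'
#' @param y Factor of class labels.
#' @param k Requested fold count; capped at the smallest class size so
#'   every fold's training part keeps all classes.
#' @param seed Integer seed.
#' @return Integer fold id per sample.
#' @export
make_folds <- function(y, k = 5L, seed = 1L) {
  y <- as.factor(y)
  k <- max(2L, min(k, min(table(y))))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' @keywords internal
#' Cross-validated accuracy of a random forest on a feature subset.
cv_accuracy <- function(x, y, cols, fold, seed = 1L, num_trees = 100) {
  if (length(cols) == 0) return(0)
  correct <- 0L
  for (f in sort(unique(fold))) {
    tr <- fold != f
    rf <- ranger::ranger(x = x[tr, cols, drop = FALSE], y = y[tr],
                         num.trees = num_trees, seed = seed, num.threads = 1)
    pred <- stats::predict(rf, data = x[!tr, cols, drop = FALSE],
                           num.threads = 1)$predictions
    correct <- correct + sum(pred == y[!tr])
  }
  correct / length(y)
}

#' Select informative fragments for one organ
#'
#' Four selection strategies over the standardized training matrix, all
#' tuned by stratified 5-fold cross-validated accuracy:
#' \describe{
#'   \item{lasso}{L1-penalized multinomial logistic regression
#'     (\pkg{glmnet}); retains every fragment with a nonzero coefficient
#'     for any class at the CV-chosen penalty. Falls back to all
#'     features (with a warning) if the penalty zeroes everything.}
#'   \item{rfe}{Recursive feature elimination, step 1, driven by random
#'     forest impurity importance; the retained subset size is the one
#'     maximizing CV accuracy (ties to the smaller subset).}
#'   \item{sfs}{Sequential forward selection: greedily add the feature
#'     that most improves CV accuracy, stop when no addition strictly
#'     improves.}
#'   \item{sbs}{Sequential backward selection: greedily drop the feature
#'     whose removal most improves CV accuracy, stop when no removal
#'     strictly improves.}
#' }
#'
#' @param method One of `"lasso"`, `"rfe"`, `"sfs"`, `"sbs"`.
#' @param x Standardized training matrix (samples x fragments).
#' @param y Factor of PMI classes (>= 2 classes present).
#' @param seed Integer seed (folds, forests and glmnet CV are seeded).
#' @param folds CV fold count (default 5, capped at the class size).
#' @return Character vector of selected column names (nonempty).
#' @export
select_features <- function(method = c("lasso", "rfe", "sfs", "sbs"),
                            x, y, seed = 1L, folds = 5L) {
  method <- match.arg(method)
  y <- as.factor(y)
  x <- as.matrix(x)
  stopifnot(nlevels(droplevels(y)) >= 2)
  sds <- apply(x, 2, stats::sd)
  if (all(sds == 0)) stop("all features have zero variance")
  if (ncol(x) == 1) return(colnames(x))
  fold <- make_folds(y, folds, seed)

  if (method == "lasso") {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
    cvfit <- glmnet::cv.glmnet(x, y, family = "multinomial",
                               type.measure = "class", foldid = fold,
                               alpha = 1)
    cf <- glmnet::coef.glmnet(cvfit, s = "lambda.min")
    nz <- Reduce(`|`, lapply(cf, function(m) as.matrix(m)[-1, 1] != 0))
    sel <- colnames(x)[nz]
    if (length(sel) == 0) {
      warning("lasso selected zero features; falling back to all features")
      sel <- colnames(x)
    }
    return(sel)
  }

  if (method == "rfe") {
    active <- colnames(x)
    elim_order <- character(0)
    while (length(active) > 1) {
      rf <- ranger::ranger(x = x[, active, drop = FALSE], y = y,
                           num.trees = 100, importance = "impurity",
                           seed = seed, num.threads = 1)
      imp <- rf$variable.importance
      worst <- names(imp)[which.min(imp)]
      elim_order <- c(worst, elim_order)  # head = eliminated last = most important
      active <- setdiff(active, worst)
    }
    ranking <- c(active, elim_order)  # importance order, best first
    scores <- vapply(seq_along(ranking), function(k) {
      cv_accuracy(x, y, ranking[seq_len(k)], fold, seed)
    }, numeric(1))
    best_k <- which.max(scores)  # which.max takes the first (smallest) maximizer
    return(sort(ranking[seq_len(best_k)]))
  }

  if (method == "sfs") {
    selected <- character(0)
    best <- -Inf
    repeat {
      cand <- setdiff(colnames(x), selected)
      if (!length(cand)) break
      sc <- vapply(cand, function(f) cv_accuracy(x, y, c(selected, f), fold, seed),
                   numeric(1))
      if (max(sc) > best) {
        best <- max(sc)
        selected <- c(selected, cand[which.max(sc)])
      } else break
    }
    if (!length(selected)) selected <- colnames(x)[1]
    return(sort(selected))
  }

  # sbs
  selected <- colnames(x)
  best <- cv_accuracy(x, y, selected, fold, seed)
  while (length(selected) > 1) {
    sc <- vapply(selected, function(f) {
      cv_accuracy(x, y, setdiff(selected, f), fold, seed)
    }, numeric(1))
    if (max(sc) > best) {
      best <- max(sc)
      selected <- setdiff(selected, selected[which.max(sc)])
    } else break
  }
  sort(selected)
}
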