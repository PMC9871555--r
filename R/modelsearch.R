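#' Selector and classifier grids
#'
#' @return Character vectors of the four selectors / five classifiers.
#' @export
pmi_selectors <- function() c("lasso", "rfe", "sbs", "sfs")

#' @rdname pmi_selectors
#' @export
pmi_classifiers <- function() c("lr", "svm", "rf", "gbdt", "mlpc")

#' Fit one (selector, classifier) pipeline for one organ
#'
#' Selects features on the (standardized) training matrix, fits the
#' classifier on the selected columns, and returns the fitted pipeline.
#' Feature selection and fitting see training data only.
#'
#' @param selector Feature-selection method, or `"none"` for all features.
#' @param classifier Classifier algorithm (see [train_classifier()]).
#' @param x_train Standardized training matrix.
#' @param y_train Factor of training PMI classes.
#' @param seed Integer seed.
#' @param params Hyperparameter overrides passed to [train_classifier()].
#' @return list of class `pmi_pipeline`: selector, classifier, features,
#'   model, seed.
#' @export
fit_pipeline <- function(selector, classifier, x_train, y_train,
                         seed = 1L, params = list()) {
  feats <- if (identical(selector, "none")) colnames(x_train) else
    select_features(selector, x_train, y_train, seed = seed)
  model <- train_classifier(classifier, x_train[, feats, drop = FALSE],
                            y_train, params = params, seed = seed)
  structure(list(selector = selector, classifier = classifier,
                 features = feats, model = model, seed = seed),
            class = "pmi_pipeline")
}

#' Evaluate a fitted pipeline on one cohort
#'
#' @param pipeline A `pmi_pipeline`.
#' @param x,y Standardized matrix and labels of the cohort.
#' @return Named metric vector (see [evaluate_predictions()]).
#' @export
evaluate_pipeline <- function(pipeline, x, y) {
  prob <- predict_proba(pipeline$model, x)
  evaluate_predictions(prob, y)
}

#' Cross-combine selectors and classifiers for one organ
#'
#' Runs the full 4 x 5 grid (20 sub-models) for one organ: each selector
#' picks fragments on the training matrix, each classifier is fitted on
#' them, and all eight validation metrics (accuracy, precision, recall,
#' AUC on internal and external cohorts) are recorded. A failing
#' pipeline is recorded with NA metrics and does not abort the rest.
#'
#' @param x_train,y_train Standardized training matrix and labels.
#' @param x_internal,y_internal Internal-validation cohort.
#' @param x_external,y_external External-validation cohort.
#' @param organ Organ label stored in the records.
#' @param seed Base seed; each grid cell derives its own.
#' @param selectors,classifiers Grids (defaults: the full study grids).
#' @return data.frame with one row per (selector, classifier): organ,
#'   selector, classifier, seed, n_features, the 8 metrics
#'   (`<metric>_internal`, `<metric>_external`), an `error` column, and
#'   `features` list-column of selected fragment columns.
#' @export
run_cross_combination <- function(x_train, y_train, x_internal, y_internal,
                                  x_external, y_external, organ = "organ",
                                  seed = 1L,
                                  selectors = pmi_selectors(),
                                  classifiers = pmi_classifiers()) {
  grid <- expand.grid(classifier = classifiers, selector = selectors,
                      stringsAsFactors = FALSE)[, c("selector", "classifier")]
  rows <- vector("list", nrow(grid))
  feat_cache <- list()
  for (i in seq_len(nrow(grid))) {
    sel <- grid$selector[i]; clf <- grid$classifier[i]
    spec_seed <- seed + 101L * match(sel, pmi_selectors_all()) +
      11L * match(clf, pmi_classifiers())
    rec <- list(organ = organ, selector = sel, classifier = clf,
                seed = spec_seed, n_features = NA_integer_, error = NA_character_)
    metrics <- rep(NA_real_, 8)
    names(metrics) <- paste0(rep(c("accuracy", "precision", "recall", "auc"), 2),
                             rep(c("_internal", "_external"), each = 4))
    feats <- NULL
    res <- tryCatch({
      # one selector run per selector (selection is classifier-independent)
      if (is.null(feat_cache[[sel]])) {
        feat_cache[[sel]] <- if (identical(sel, "none")) colnames(x_train) else
          select_features(sel, x_train, y_train, seed = seed)
      }
      feats <- feat_cache[[sel]]
      model <- train_classifier(clf, x_train[, feats, drop = FALSE], y_train,
                                seed = spec_seed)
      pl <- structure(list(selector = sel, classifier = clf, features = feats,
                           model = model, seed = spec_seed),
                      class = "pmi_pipeline")
      m_int <- evaluate_pipeline(pl, x_internal, y_internal)
      m_ext <- evaluate_pipeline(pl, x_external, y_external)
      list(int = m_int, ext = m_ext)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      rec$error <- conditionMessage(res)
    } else {
      metrics[1:4] <- res$int
      metrics[5:8] <- res$ext
      rec$n_features <- length(feats)
    }
    rows[[i]] <- c(rec, as.list(metrics), list(features = list(feats)))
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    d <- as.data.frame(r[setdiff(names(r), "features")], stringsAsFactors = FALSE)
    d
  }))
  out$features <- lapply(rows, function(r) r$features[[1]])
  out
}

#' @keywords internal
pmi_selectors_all <- function() c(pmi_selectors(), "none")
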