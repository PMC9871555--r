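#' Train one of the five base classifiers
#'
#' Wraps the five learning algorithms of the sub-model grid behind one
#' interface with per-class probability output: multinomial logistic
#' regression (`"lr"`), an RBF support-vector machine with probability
#' calibration (`"svm"`), a 100-tree random forest (`"rf"`), gradient
#' boosted trees (`"gbdt"`, 100 rounds of depth 3), and a one-hidden-layer
#' multilayer perceptron (`"mlpc"`, 100 units, weight decay). The study
#' protocol fixes only the algorithm family; these hyperparameters are the
#' package defaults and can be overridden via `params`.
#'
#' @param algo One of `"lr"`, `"svm"`, `"rf"`, `"gbdt"`, `"mlpc"`.
#' @param x Numeric matrix (standardized, restricted to selected features).
#' @param y Factor of PMI classes; every level must occur in `y`.
#' @param params Named list of hyperparameter overrides.
#' @param seed Integer seed (all stochastic fits are seeded).
#' @return Object of class `pmi_model`.
#' @export
train_classifier <- function(algo = c("lr", "svm", "rf", "gbdt", "mlpc"),
                             x, y, params = list(), seed = 1L) {
  algo <- match.arg(algo)
  y <- as.factor(y)
  if (any(table(y) == 0)) {
    stop("class absent from training data: ",
         paste(levels(y)[table(y) == 0], collapse = ", "))
  }
  x <- as.matrix(x)
  p <- ncol(x)
  K <- nlevels(y)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fit <- switch(algo,
    lr = {
      d <- data.frame(.y = y, x, check.names = FALSE)
      nnet::multinom(.y ~ ., data = d, trace = FALSE, maxit = 300,
                     decay = params$decay %||% 0.01,
                     MaxNWts = 100000)
    },
    svm = e1071::svm(x, y, kernel = "radial", probability = TRUE,
                     cost = params$cost %||% 1,
                     gamma = params$gamma %||% (1 / p)),
    rf = ranger::ranger(x = x, y = y, probability = TRUE,
                        num.trees = params$num_trees %||% 100,
                        seed = seed, num.threads = 1),
    gbdt = {
      dtrain <- xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L)
      xgboost::xgb.train(params = list(objective = "multi:softprob",
                                       num_class = K,
                                       max_depth = params$max_depth %||% 3,
                                       eta = params$eta %||% 0.1,
                                       nthread = 1,
                                       seed = seed),
                         data = dtrain,
                         nrounds = params$nrounds %||% 100,
                         verbose = 0)
    },
    mlpc = nnet::nnet(x = x, y = nnet::class.ind(y), softmax = TRUE,
                      size = params$size %||% 100,
                      decay = params$decay %||% 0.01,
                      maxit = params$maxit %||% 200,
                      MaxNWts = 100000, trace = FALSE)
  )
  structure(list(algo = algo, fit = fit, levels = levels(y),
                 features = colnames(x), seed = seed),
            class = "pmi_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-class probability predictions
#'
#' Every `pmi_model` exposes class probabilities over the full training
#' class set; rows are renormalized to sum to exactly 1.
#'
#' @param model A `pmi_model`.
#' @param x New-data matrix with (at least) the model's feature columns.
#' @return Probability matrix, columns named by class level in day order.
#' @export
predict_proba <- function(model, x) {
  x <- as.matrix(x)[, model$features, drop = FALSE]
  lev <- model$levels
  prob <- switch(model$algo,
    lr = {
      d <- data.frame(x, check.names = FALSE)
      pr <- stats::predict(model$fit, newdata = d, type = "probs")
      if (is.null(dim(pr))) {  # two-class multinom returns P(level 2)
        pr <- cbind(1 - pr, pr)
        colnames(pr) <- lev
      }
      pr <- rbind(pr)  # single-row predictions come back as a vector
      if (is.null(colnames(pr))) colnames(pr) <- lev
      pr
    },
    svm = {
      pr <- stats::predict(model$fit, x, probability = TRUE)
      attr(pr, "probabilities")
    },
    rf = stats::predict(model$fit, data = x, num.threads = 1)$predictions,
    gbdt = {
      pr <- stats::predict(model$fit, xgboost::xgb.DMatrix(x))
      if (is.null(dim(pr))) pr <- matrix(pr, ncol = length(lev), byrow = TRUE)
      colnames(pr) <- lev
      pr
    },
    mlpc = {
      pr <- stats::predict(model$fit, x)
      colnames(pr) <- lev
      pr
    }
  )
  prob <- prob[, lev, drop = FALSE]
  prob <- prob / rowSums(prob)
  rownames(prob) <- rownames(x)
  prob
}
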