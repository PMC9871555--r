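test_that("every selector recovers a planted two-feature signal", {
  # class identity needs both informative features; the rest is pure noise
  d <- separable_data(n_per_class = 12, classes = 3, p = 6, informative = 2,
                      seed = 3)
  for (m in pmi_selectors()) {
    sel <- suppressWarnings(select_features(m, d$x, d$y, seed = 1))
    expect_true(all(c("F1", "F2") %in% sel),
                info = paste(m, "selected:", paste(sel, collapse = ",")))
  }
})

test_that("forward selection starts with the single informative feature", {
  d <- separable_data(n_per_class = 12, classes = 2, p = 5, informative = 1,
                      seed = 9)
  sel <- select_features("sfs", d$x, d$y, seed = 1)
  expect_true("F1" %in% sel)
  expect_lte(length(sel), 2)  # noise features add nothing once F1 is in
})

test_that("selector preconditions are enforced", {
  d <- separable_data(seed = 2)
  flat <- matrix(0, 20, 3, dimnames = list(NULL, paste0("F", 1:3)))
  expect_error(select_features("lasso", flat, factor(rep(1:2, 10))), "variance")
  expect_error(select_features("sfs", d$x, factor(rep("a", nrow(d$x)))))
})

test_that("all five classifiers fit separable data and emit valid probabilities", {
  d <- separable_data(n_per_class = 15, classes = 2, p = 4, informative = 2,
                      seed = 5)
  for (algo in pmi_classifiers()) {
    fit <- train_classifier(algo, d$x, d$y, seed = 1)
    prob <- predict_proba(fit, d$x)
    expect_equal(unname(rowSums(prob)), rep(1, nrow(d$x)), tolerance = 1e-9)
    expect_true(all(prob >= 0))
    acc <- mean(predict_classes(prob) == d$y)
    expect_equal(acc, 1.0, info = algo)
  }
})

test_that("stochastic classifiers are reproducible under a fixed seed", {
  d <- separable_data(n_per_class = 10, classes = 3, p = 5, seed = 6)
  for (algo in c("rf", "gbdt", "mlpc")) {
    p1 <- predict_proba(train_classifier(algo, d$x, d$y, seed = 7), d$x)
    p2 <- predict_proba(train_classifier(algo, d$x, d$y, seed = 7), d$x)
    expect_identical(p1, p2, info = algo)
  }
})

test_that("training rejects labels with absent classes", {
  d <- separable_data(seed = 2)
  y_bad <- factor(d$y, levels = c(levels(d$y), "99"))
  expect_error(train_classifier("rf", d$x, y_bad), "absent")
})

test_that("metrics follow their definitions", {
  # 20 of 28 correct
  truth <- factor(rep(1:14, 2))
  pred <- truth
  pred[1:8] <- factor(c(2:9))
  m <- evaluate_predictions(prob = NULL, truth, predicted = pred)
  expect_equal(unname(m["accuracy"]), 20 / 28, tolerance = 1e-12)
  expect_true(is.na(m["auc"]))  # no probability scores available

  perfect <- informative_prob(truth, confidence = 10)
  m2 <- evaluate_predictions(perfect, truth)
  expect_equal(unname(m2[c("accuracy", "precision", "recall", "auc")]),
               c(1, 1, 1, 1))
})

test_that("uniform-random scores give chance-level macro AUC", {
  set.seed(8)
  truth <- factor(sample(1:4, 2000, replace = TRUE))
  prob <- matrix(runif(2000 * 4), ncol = 4, dimnames = list(NULL, levels(truth)))
  prob <- prob / rowSums(prob)
  m <- evaluate_predictions(prob, truth)
  expect_equal(unname(m["auc"]), 0.5, tolerance = 0.03)
})

test_that("accuracy equals the confusion-matrix trace over its total", {
  set.seed(3)
  truth <- factor(sample(1:5, 100, replace = TRUE), levels = 1:5)
  pred <- factor(sample(1:5, 100, replace = TRUE), levels = 1:5)
  m <- evaluate_predictions(NULL, truth, pred)
  cm <- report_confusion(pred, truth)
  expect_equal(unname(m["accuracy"]),
               sum(diag(cm$matrix)) / sum(cm$matrix))
})

test_that("the cross-combination grid yields one record per sub-model", {
  d <- separable_data(n_per_class = 14, classes = 3, p = 5, informative = 2,
                      seed = 4)
  idx <- rep(rep(c(TRUE, FALSE), c(5, 2)), 6)  # 30 train / 12 held-out
  recs <- suppressWarnings(run_cross_combination(
    d$x[idx, ], d$y[idx], d$x[!idx, ], d$y[!idx], d$x[!idx, ], d$y[!idx],
    organ = "toy", seed = 1,
    selectors = c("lasso", "sfs"), classifiers = c("lr", "rf", "gbdt")))
  expect_equal(nrow(recs), 6)
  expect_true(all(is.na(recs$error)))
  metric_cols <- grep("_(internal|external)$", names(recs), value = TRUE)
  expect_true(all(as.matrix(recs[, metric_cols]) >= 0 &
                    as.matrix(recs[, metric_cols]) <= 1))
  # leakage guard: features were chosen on training data only, and the
  # record stores them for audit
  expect_true(all(lengths(recs$features) >= 1))

  recs2 <- suppressWarnings(run_cross_combination(
    d$x[idx, ], d$y[idx], d$x[!idx, ], d$y[!idx], d$x[!idx, ], d$y[!idx],
    organ = "toy", seed = 1,
    selectors = c("lasso", "sfs"), classifiers = c("lr", "rf", "gbdt")))
  expect_identical(recs, recs2)
})

test_that("a failing sub-model is recorded without aborting the grid", {
  d <- separable_data(n_per_class = 8, classes = 2, p = 3, seed = 10)
  # sabotage: external matrix missing the feature columns makes prediction fail
  bad_ext <- matrix(0, 4, 1, dimnames = list(NULL, "Z"))
  recs <- suppressWarnings(run_cross_combination(
    d$x, d$y, d$x, d$y, bad_ext, d$y[1:4], organ = "toy", seed = 1,
    selectors = "lasso", classifiers = c("lr", "rf")))
  expect_equal(nrow(recs), 2)
  expect_true(all(!is.na(recs$error)))
})
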