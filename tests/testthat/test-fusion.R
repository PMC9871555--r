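two_class <- function(p) matrix(p, ncol = 2, byrow = TRUE,
                                dimnames = list(NULL, c("0", "1")))

test_that("soft voting averages probabilities and breaks ties early", {
  a <- two_class(c(0.6, 0.4))
  b <- two_class(c(0.2, 0.8))
  one <- soft_vote(list(a))
  expect_equal(one$prob, a)
  expect_equal(as.character(one$predicted), "0")

  fused <- soft_vote(list(a, b))
  expect_equal(unname(fused$prob[1, ]), c(0.4, 0.6))
  expect_equal(as.character(fused$predicted), "1")

  tie <- suppressMessages(soft_vote(list(a, two_class(c(0.4, 0.6)))))
  expect_equal(unname(tie$prob[1, ]), c(0.5, 0.5))
  expect_equal(as.character(tie$predicted), "0")  # earlier PMI class wins ties
})

test_that("weighted voting reduces to the documented degenerate cases", {
  a <- two_class(c(0.6, 0.4))
  b <- two_class(c(0.2, 0.8))
  expect_equal(soft_weighted_vote(list(a, b), c(1, 1))$prob,
               soft_vote(list(a, b))$prob)
  expect_equal(soft_weighted_vote(list(a, b), c(1, 0))$prob, a)
  mix <- suppressMessages(soft_weighted_vote(list(a, b), c(0.75, 0.25)))
  expect_equal(unname(mix$prob[1, ]), c(0.5, 0.5))
  expect_equal(as.character(mix$predicted), "0")

  expect_error(soft_weighted_vote(list(a, b), c(-1, 2)), "nonnegative")
  expect_error(soft_weighted_vote(list(a, b), c(0, 0)), "zero")
  bad <- two_class(c(0.5, 0.5)); colnames(bad) <- c("x", "y")
  expect_error(soft_vote(list(a, bad)), "class set")
})

test_that("fused probabilities are valid distributions", {
  set.seed(2)
  mk <- function() {
    m <- matrix(runif(40), 10, 4, dimnames = list(NULL, letters[1:4]))
    m / rowSums(m)
  }
  for (i in 1:10) {
    fused <- soft_weighted_vote(list(mk(), mk(), mk()), runif(3))
    expect_true(all(fused$prob >= 0))
    expect_equal(unname(rowSums(fused$prob)), rep(1, 10), tolerance = 1e-9)
  }
})

test_that("stacking learns from perfect members and is seed-deterministic", {
  set.seed(4)
  y <- factor(rep(1:3, each = 10))
  x <- matrix(rnorm(90), 30, 3, dimnames = list(NULL, c("a", "b", "c")))
  x[, 1] <- as.integer(y) + rnorm(30, 0, 0.05)  # member signal
  fit_funs <- list(function(x, y, s) train_classifier("lr", x, y, seed = s),
                   function(x, y, s) train_classifier("rf", x, y, seed = s))
  st <- fit_stacking(list(x, x), y, fit_funs, folds = 5, seed = 1)
  pred <- predict_stacking(st, list(x, x))
  expect_equal(mean(pred$predicted == y), 1.0)

  st2 <- fit_stacking(list(x, x), y, fit_funs, folds = 5, seed = 1)
  expect_identical(st$meta_features, st2$meta_features)
})

test_that("stacking is not dragged down by a pure-noise member", {
  set.seed(5)
  y <- factor(rep(1:3, each = 14))
  signal <- matrix(rnorm(42 * 2), 42, 2, dimnames = list(NULL, c("s1", "s2")))
  signal[, 1] <- signal[, 1] + 4 * as.integer(y)
  noise <- matrix(rnorm(42 * 2), 42, 2, dimnames = list(NULL, c("n1", "n2")))
  test_idx <- rep(c(FALSE, TRUE), c(30, 12))
  perm <- sample(42)
  tr <- perm[!test_idx]; te <- perm[test_idx]
  fit_funs <- list(function(x, y, s) train_classifier("lr", x, y, seed = s),
                   function(x, y, s) train_classifier("lr", x, y, seed = s))
  st <- fit_stacking(list(signal[tr, ], noise[tr, ]), y[tr], fit_funs,
                     folds = 3, seed = 2)
  stack_acc <- mean(predict_stacking(st, list(signal[te, ], noise[te, ]))$predicted == y[te])
  solo <- train_classifier("lr", signal[tr, ], y[tr], seed = 2)
  solo_acc <- mean(predict_classes(predict_proba(solo, signal[te, ])) == y[te])
  expect_gte(stack_acc, solo_acc - 0.25)  # within sampling error of the informative member
})

test_that("stacking rejects folds that lose a class", {
  y <- factor(c(rep(1, 10), rep(2, 10), 3))  # class 3 has one sample
  x <- matrix(rnorm(42), 21, 2, dimnames = list(NULL, c("a", "b")))
  fit_funs <- list(function(x, y, s) train_classifier("lr", x, y, seed = s),
                   function(x, y, s) train_classifier("lr", x, y, seed = s))
  expect_error(fit_stacking(list(x, x), y, fit_funs, folds = 2, seed = 1),
               "missing a class")
})

test_that("multi-organ fusion is keyed by rat id", {
  y <- factor(rep(1:2, each = 4))
  p <- informative_prob(y, confidence = 5, seed = 3)
  rownames(p) <- paste0("R", 1:8)
  organs <- list(lung = p, liver = p, kidney = p, muscle = p)
  fused <- fuse_organs(organs, "soft_voting")
  expect_equal(mean(fused$predicted == y[order(paste0("R", 1:8))]), 1.0)

  shuffled <- organs
  shuffled$liver <- shuffled$liver[sample(8), , drop = FALSE]
  expect_equal(fuse_organs(shuffled, "soft_voting")$prob, fused$prob)

  missing <- organs
  missing$lung <- missing$lung[-3, , drop = FALSE]
  expect_error(fuse_organs(missing, "soft_voting"), "R3")
})

test_that("pruning removes exactly a planted adversary and matches the subset oracle", {
  # three diffuse but complementary members: member i is uninformative on
  # the samples of class i + 1 and mildly informative elsewhere, so each
  # single member errs on one class, any pair is perfect, and the
  # mirrored-one-hot adversary drags every subset containing it down
  y <- factor(rep(1:4, each = 6))
  K <- nlevels(y)
  diffuse_member <- function(blind_class) {
    p <- matrix(0.2, length(y), K, dimnames = list(NULL, levels(y)))
    p[cbind(seq_along(y), as.integer(y))] <- 0.4
    blind <- as.integer(y) == blind_class
    p[blind, ] <- 1 / K
    p / rowSums(p)
  }
  members <- list(g1 = diffuse_member(2), g2 = diffuse_member(3),
                  g3 = diffuse_member(4), adv = adversarial_prob(y))
  eval_fun <- function(ss) {
    mean(suppressMessages(soft_vote(members[ss]))$predicted == y)
  }
  res <- prune_ensemble(names(members), eval_fun)
  expect_setequal(res$active_members, c("g1", "g2", "g3"))
  expect_equal(res$trajectory$removed[2], "adv")

  # exhaustive oracle over all 15 nonempty subsets: the greedy result
  # attains the oracle's best score
  subsets <- unlist(lapply(1:4, function(k) {
    asplit(combn(names(members), k), 2)
  }), recursive = FALSE)
  scores <- vapply(subsets, function(ss) eval_fun(as.character(ss)), numeric(1))
  expect_equal(res$score, max(scores))
  expect_false("adv" %in% as.character(subsets[[which.max(scores)]]))
})

test_that("pruning never returns a score below the full ensemble's", {
  set.seed(7)
  y <- factor(rep(1:3, each = 8))
  for (i in 1:10) {
    members <- lapply(1:4, function(j) {
      informative_prob(y, confidence = runif(1, 0, 0.6), seed = 10 * i + j)
    })
    names(members) <- paste0("m", 1:4)
    eval_fun <- function(ss) mean(soft_vote(members[ss])$predicted == y)
    res <- prune_ensemble(names(members), eval_fun)
    expect_gte(res$score, eval_fun(names(members)))
    expect_equal(res$trajectory$score[1], eval_fun(names(members)))
  }
  single <- prune_ensemble("only", function(ss) 0.5)
  expect_equal(single$active_members, "only")
})

test_that("single-organ ensembles cover the selector-by-combiner grid", {
  d <- separable_data(n_per_class = 12, classes = 3, p = 4, informative = 2,
                      seed = 11)
  idx <- rep(rep(c(TRUE, FALSE), c(8, 4)), 3)
  recs <- suppressWarnings(single_organ_ensembles(
    d$x[idx, ], d$y[idx], d$x[!idx, ], d$y[!idx], d$x[!idx, ], d$y[!idx],
    organ = "toy", seed = 1, selectors = "lasso", folds = 3))
  expect_equal(nrow(recs), 3)  # one selector x three combiners
  expect_setequal(recs$combiner,
                  c("stacking", "soft_voting", "soft_weighted_voting"))
  metric_cols <- grep("_(internal|external)$", names(recs), value = TRUE)
  expect_true(all(as.matrix(recs[, metric_cols]) >= 0 &
                    as.matrix(recs[, metric_cols]) <= 1))
})
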