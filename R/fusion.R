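#' Soft-voting fusion of member probabilities
#'
#' Fused class probabilities are the unweighted mean of the member
#' probability matrices; the prediction is the argmax with ties broken
#' toward the earlier PMI class.
#'
#' @param prob_list List of probability matrices over the same classes
#'   (identical column names) and samples (identical row count/order).
#' @return list: `prob` (fused matrix), `predicted` (factor).
#' @export
soft_vote <- function(prob_list) {
  soft_weighted_vote(prob_list, rep(1, length(prob_list)))
}

#' Soft-weighted-voting fusion
#'
#' Fused probability is the weighted mean of member probabilities with
#' weights normalized to sum to one.
#'
#' @param prob_list As in [soft_vote()].
#' @param weights Nonnegative member weights, not all zero.
#' @return list: `prob`, `predicted`.
#' @export
soft_weighted_vote <- function(prob_list, weights) {
  stopifnot(length(prob_list) >= 1, length(weights) == length(prob_list))
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (sum(weights) == 0) stop("weights must not all be zero")
  cls <- colnames(prob_list[[1]])
  n <- nrow(prob_list[[1]])
  for (p in prob_list) {
    if (!identical(colnames(p), cls) || nrow(p) != n) {
      stop("members must share the same class set and sample count")
    }
  }
  w <- weights / sum(weights)
  fused <- Reduce(`+`, Map(function(p, wi) wi * p, prob_list, w))
  list(prob = fused, predicted = predict_classes(fused, cls))
}

#' Fit a stacking ensemble
#'
#' Meta-features are out-of-fold member class probabilities on the
#' training data: for each of `folds` stratified folds every member is
#' refit on the remaining folds (on its own feature matrix) and predicts
#' the held-out rows. A multinomial logistic meta-learner is fit on the
#' concatenated meta-features, and the members are finally refit on the
#' full training data.
#'
#' @param member_x List of training matrices, one per member, with rows
#'   aligned to the same samples.
#' @param y Factor of training labels.
#' @param fit_funs List of functions `function(x, y, seed)` returning a
#'   `pmi_model`, one per member.
#' @param folds Stratified CV fold count (default 5; >= 2).
#' @param seed Integer seed (folds and member refits).
#' @return list of class `pmi_stacking`: `members` (full-data fits),
#'   `meta` (multinom fit), `levels`, `meta_features`.
#' @export
fit_stacking <- function(member_x, y, fit_funs, folds = 5L, seed = 1L) {
  stopifnot(length(member_x) >= 2, length(fit_funs) == length(member_x), folds >= 2)
  y <- as.factor(y)
  n <- nrow(member_x[[1]])
  stopifnot(all(vapply(member_x, nrow, integer(1)) == n), length(y) == n)
  fold <- make_folds(y, folds, seed)
  if (any(tapply(seq_len(n), fold, function(i) nlevels(droplevels(y[-i]))) < nlevels(y))) {
    stop("stratification failed: a fold's training part is missing a class")
  }
  K <- nlevels(y)
  meta <- matrix(NA_real_, n, K * length(member_x))
  for (f in sort(unique(fold))) {
    tr <- fold != f
    for (m in seq_along(member_x)) {
      fit <- fit_funs[[m]](member_x[[m]][tr, , drop = FALSE], y[tr],
                           seed + 7L * f + m)
      meta[!tr, (m - 1) * K + seq_len(K)] <-
        predict_proba(fit, member_x[[m]][!tr, , drop = FALSE])
    }
  }
  colnames(meta) <- paste0("m", rep(seq_along(member_x), each = K),
                           "_", rep(levels(y), length(member_x)))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  d <- data.frame(.y = y, meta, check.names = FALSE)
  meta_fit <- nnet::multinom(.y ~ ., data = d, trace = FALSE, maxit = 300,
                             decay = 0.01, MaxNWts = 100000)
  members <- lapply(seq_along(member_x), function(m) {
    fit_funs[[m]](member_x[[m]], y, seed + m)
  })
  structure(list(members = members, meta = meta_fit, levels = levels(y),
                 meta_features = meta, fold = fold, seed = seed),
            class = "pmi_stacking")
}

#' Predict from a stacking ensemble
#'
#' @param stack A `pmi_stacking`.
#' @param member_x_new List of new-data matrices, one per member,
#'   row-aligned.
#' @return list: `prob` (meta-learner class probabilities), `predicted`.
#' @export
predict_stacking <- function(stack, member_x_new) {
  K <- length(stack$levels)
  meta <- do.call(cbind, lapply(seq_along(stack$members), function(m) {
    predict_proba(stack$members[[m]], member_x_new[[m]])
  }))
  colnames(meta) <- colnames(stack$meta_features)
  pr <- stats::predict(stack$meta, newdata = data.frame(meta, check.names = FALSE),
                       type = "probs")
  if (is.null(dim(pr))) {
    pr <- if (K == 2) cbind(1 - pr, pr) else rbind(pr)
  }
  colnames(pr) <- stack$levels
  pr <- pr / rowSums(pr)
  rownames(pr) <- rownames(member_x_new[[1]])
  list(prob = pr, predicted = predict_classes(pr, stack$levels))
}

#' Align per-organ probability matrices by rat
#'
#' Multi-organ fusion combines one probability vector per organ for the
#' same animal; rows are therefore keyed and joined by rat id. Every rat
#' must have all organs.
#'
#' @param prob_by_organ Named list (by organ) of probability matrices
#'   with rat ids as rownames.
#' @return The list with rows reordered to a common sorted rat-id key.
#' @export
align_by_rat <- function(prob_by_organ) {
  ids <- lapply(prob_by_organ, rownames)
  common <- sort(Reduce(intersect, ids))
  missing <- lapply(ids, function(i) setdiff(sort(unique(unlist(ids))), i))
  bad <- unique(unlist(missing))
  if (length(bad)) stop("rat(s) missing an organ sample: ", paste(bad, collapse = ", "))
  lapply(prob_by_organ, function(p) p[common, , drop = FALSE])
}

#' Fuse per-organ predictions into one PMI call per rat
#'
#' @param prob_by_organ Named list of per-organ class-probability
#'   matrices (rownames = rat ids).
#' @param combiner `"soft_voting"`, `"soft_weighted_voting"`, or
#'   `"stacking"` (which requires a prefit `stack` whose members map the
#'   supplied matrices).
#' @param weights Member weights for weighted voting (e.g., each organ
#'   pipeline's internal-validation accuracy).
#' @param stack A `pmi_stacking` fit on per-organ training matrices; for
#'   `combiner = "stacking"` pass the per-organ feature matrices in
#'   `member_x_new` instead of probabilities.
#' @param member_x_new Per-organ feature matrices for stacking predict.
#' @return list: `prob`, `predicted` (one row/element per rat, rat ids
#'   as names).
#' @export
fuse_organs <- function(prob_by_organ = NULL,
                        combiner = c("soft_voting", "soft_weighted_voting", "stacking"),
                        weights = NULL, stack = NULL, member_x_new = NULL) {
  combiner <- match.arg(combiner)
  if (combiner == "stacking") {
    stopifnot(!is.null(stack), !is.null(member_x_new))
    return(predict_stacking(stack, member_x_new))
  }
  aligned <- align_by_rat(prob_by_organ)
  if (combiner == "soft_voting") return(soft_vote(aligned))
  stopifnot(!is.null(weights))
  soft_weighted_vote(aligned, weights)
}

#' Greedy backward ensemble pruning
#'
#' Starting from all members, repeatedly evaluates the removal of each
#' active member and removes the one yielding the largest strict
#' improvement of the (internal-validation) score; stops when no removal
#' strictly improves. Ties on improvement are broken by removing the
#' member with the lowest individual score.
#'
#' @param members Character vector of member identifiers.
#' @param eval_fun Function taking a character subset of `members` and
#'   returning a scalar score (higher is better), evaluated on internal
#'   validation only.
#' @return list: `active_members`, `score` (final), `trajectory`
#'   (data.frame step, removed, score).
#' @export
prune_ensemble <- function(members, eval_fun) {
  stopifnot(length(members) >= 1)
  active <- members
  score <- eval_fun(active)
  traj <- data.frame(step = 0L, removed = NA_character_, score = score,
                     stringsAsFactors = FALSE)
  step <- 0L
  while (length(active) > 1) {
    cand <- vapply(active, function(m) eval_fun(setdiff(active, m)), numeric(1))
    if (max(cand) <= score) break
    best <- active[cand == max(cand)]
    if (length(best) > 1) {
      indiv <- vapply(best, function(m) eval_fun(m), numeric(1))
      best <- best[which.min(indiv)]
    } else best <- best[1]
    active <- setdiff(active, best)
    score <- max(cand)
    step <- step + 1L
    traj <- rbind(traj, data.frame(step = step, removed = best, score = score,
                                   stringsAsFactors = FALSE))
  }
  list(active_members = active, score = score, trajectory = traj)
}

#' Single-organ ensembles over the five classifiers
#'
#' For one organ and one selector, the five base classifiers are trained
#' on the selector's fragments and combined by stacking, soft voting and
#' soft-weighted voting (weights = member internal-validation
#' accuracies, normalized). Run over the four selectors this mirrors the
#' selector-by-combiner ensemble grid of the single-organ analysis.
#'
#' @param x_train,y_train,x_internal,y_internal,x_external,y_external
#'   Standardized cohort matrices and labels.
#' @param organ Organ label for the records.
#' @param seed Base seed.
#' @param selectors Selector grid (default all four).
#' @param folds Stacking folds.
#' @return data.frame of evaluation records: organ, selector, combiner,
#'   the 8 metrics, n_features.
#' @export
single_organ_ensembles <- function(x_train, y_train, x_internal, y_internal,
                                   x_external, y_external, organ = "organ",
                                   seed = 1L, selectors = pmi_selectors(),
                                   folds = 5L) {
  rows <- list()
  for (sel in selectors) {
    feats <- select_features(sel, x_train, y_train, seed = seed)
    xt <- x_train[, feats, drop = FALSE]
    xi <- x_internal[, feats, drop = FALSE]
    xe <- x_external[, feats, drop = FALSE]
    algos <- pmi_classifiers()
    fits <- lapply(seq_along(algos), function(a) {
      train_classifier(algos[a], xt, y_train, seed = seed + 11L * a)
    })
    p_int <- lapply(fits, predict_proba, x = xi)
    p_ext <- lapply(fits, predict_proba, x = xe)
    w <- vapply(p_int, function(p) {
      unname(evaluate_predictions(p, y_internal)["accuracy"])
    }, numeric(1))
    if (sum(w) == 0) w <- rep(1, length(w))

    fit_funs <- lapply(algos, function(a) function(x, y, s) train_classifier(a, x, y, seed = s))
    stack <- fit_stacking(rep(list(xt), length(algos)), y_train, fit_funs,
                          folds = folds, seed = seed)
    res <- list(
      stacking = list(int = predict_stacking(stack, rep(list(xi), length(algos))),
                      ext = predict_stacking(stack, rep(list(xe), length(algos)))),
      soft_voting = list(int = soft_vote(p_int), ext = soft_vote(p_ext)),
      soft_weighted_voting = list(int = soft_weighted_vote(p_int, w),
                                  ext = soft_weighted_vote(p_ext, w))
    )
    for (cmb in names(res)) {
      mi <- evaluate_predictions(res[[cmb]]$int$prob, y_internal)
      me <- evaluate_predictions(res[[cmb]]$ext$prob, y_external)
      rows[[paste(sel, cmb)]] <- data.frame(
        organ = organ, selector = sel, combiner = cmb,
        n_features = length(feats),
        accuracy_internal = mi["accuracy"], precision_internal = mi["precision"],
        recall_internal = mi["recall"], auc_internal = mi["auc"],
        accuracy_external = me["accuracy"], precision_external = me["precision"],
        recall_external = me["recall"], auc_external = me["auc"],
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  do.call(rbind, rows)
}
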