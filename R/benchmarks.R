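#' Single-linkage clustering oracle for peak matching
#'
#' Independent reference partition for the greedy matcher: two peaks are
#' linked when their relative migration deviation is below the
#' tolerance, and clusters are the transitive closure of the link
#' relation. For instances whose clusters are separated by more than
#' twice the tolerance this equals any reasonable matching rule.
#'
#' @param times Vector of migration times.
#' @param tolerance Relative deviation threshold.
#' @return Integer cluster id per peak, numbered by ascending cluster mean.
#' @export
cluster_oracle <- function(times, tolerance = 0.02) {
  n <- length(times)
  id <- seq_len(n)
  find <- function(i) { while (id[i] != i) { id[i] <<- id[id[i]]; i <- id[i] }; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j) {
      m <- mean(c(times[i], times[j]))
      if (abs(times[i] - times[j]) / m < tolerance) {
        id[max(find(i), find(j))] <- min(find(i), find(j))
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  means <- tapply(times, root, mean)
  rk <- rank(means, ties.method = "first")
  as.integer(rk[as.character(root)])
}

#' Random well-separated peak instance
#'
#' Draws `k` cluster centers whose consecutive relative gaps exceed
#' `2 * tolerance` and scatters `n` peaks tightly around them, for
#' oracle-equivalence and permutation-stability checks of the matcher.
#'
#' @param n Number of peaks (<= 30 in the acceptance checks).
#' @param k Number of clusters.
#' @param tolerance Matching tolerance the separation is relative to.
#' @param seed Integer seed.
#' @return list: `times`, `truth` (cluster id per peak, by ascending mean).
#' @export
random_peak_instance <- function(n = 30, k = 5, tolerance = 0.02, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  centers <- numeric(k)
  centers[1] <- stats::runif(1, 20, 25)
  for (j in seq_len(k - 1)) {
    gap <- stats::runif(1, 2.5, 6) * tolerance  # > 2x tolerance separation
    centers[j + 1] <- centers[j] * (1 + gap)
  }
  assign <- sort(sample(rep_len(seq_len(k), n)))
  times <- centers[assign] * (1 + stats::rnorm(n, 0, tolerance / 8))
  ord <- sample(n)  # shuffle input order
  list(times = times[ord], truth = assign[ord])
}

#' Brute-force rank-score oracle
#'
#' Enumerates, per metric column, every ordering of the models that is
#' consistent with sorting the column from worst to best, assigns
#' positions 1..M, and averages the position of each model over all
#' consistent orderings. Totals are the sums over the eight columns.
#' Feasible for small M (the acceptance check uses M <= 4).
#'
#' @param records As in [rank_models()].
#' @return Named numeric vector of total scores per model id.
#' @export
rank_oracle <- function(records) {
  metric_cols <- paste0(rep(c("accuracy", "precision", "recall", "auc"), 2),
                        rep(c("_internal", "_external"), each = 4))
  model <- if ("model" %in% names(records)) records$model else
    paste(records$selector, records$classifier, sep = "+")
  M <- nrow(records)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  all_perms <- perms(seq_len(M))
  total <- stats::setNames(numeric(M), model)
  for (mc in metric_cols) {
    v <- records[[mc]]
    score <- numeric(M); count <- 0
    for (p in all_perms) {
      if (all(diff(v[p]) >= 0)) {  # worst..best ordering consistent with values
        score[p] <- score[p] + seq_len(M)
        count <- count + 1
      }
    }
    total <- total + score / count
  }
  total
}

#' Multi-organ fusion benchmark on the default synthetic scenario
#'
#' Runs the compact fusion pipeline for one seed: simulate the default
#' design with organ-specific noise, build and filter the catalog, split
#' rats 70/30, fit one LASSO + random-forest pipeline per organ, and
#' compare each single organ's external-validation accuracy with the
#' soft-voting fusion of the four organ pipelines.
#'
#' @param seed Integer seed (drives simulation, split and fits).
#' @param design,kinetics Study conditions (defaults: the study design
#'   and default kinetics).
#' @param selector,classifier Per-organ pipeline (default LASSO + RF,
#'   the study's best single-organ sub-model family).
#' @return list: `single_external` (named accuracies), `fused_external`,
#'   `fused_internal`, plus the aligned internal/external probability
#'   lists and labels for downstream pruning checks.
#' @export
fusion_benchmark <- function(seed, design = study_design(),
                             kinetics = kinetics_params(),
                             selector = "lasso", classifier = "rf") {
  config <- experiment_config(design = design, kinetics = kinetics,
                              seed = as.integer(seed))
  data <- prepare_study_data(config)
  organs <- design$organs
  p_int <- list(); p_ext <- list(); single_ext <- numeric(0)
  for (organ in organs) {
    d <- data$organs[[organ]]
    pl <- fit_pipeline(selector, classifier, d$x_train, d$y_train,
                       seed = stage_seed(config, "search"))
    p_int[[organ]] <- organ_prob_by_rat(pl, d$x_internal, d$rat_internal)
    p_ext[[organ]] <- organ_prob_by_rat(pl, d$x_external, d$rat_external)
  }
  d1 <- data$organs[[organs[1]]]
  y_int <- d1$y_internal[order(d1$rat_internal)]
  y_ext <- d1$y_external[order(d1$rat_external)]
  for (organ in organs) {
    single_ext[organ] <- mean(predict_classes(p_ext[[organ]]) == y_ext)
  }
  fused_ext <- soft_vote(p_ext)
  fused_int <- soft_vote(p_int)
  list(single_external = single_ext,
       fused_external = mean(fused_ext$predicted == y_ext),
       fused_internal = mean(fused_int$predicted == y_int),
       p_int = p_int, p_ext = p_ext, y_int = y_int, y_ext = y_ext)
}

#' Adversarial member probabilities
#'
#' Builds a probability matrix anti-correlated with the truth: for a rat
#' of class k (of K, in day order) the mass sits on the mirrored class
#' K + 1 - k (by default all of it, i.e. a mirrored one-hot).
#'
#' @param truth Factor of true classes.
#' @param concentration Mass on the mirrored class (default 1).
#' @return Probability matrix (rows = samples, columns = class levels).
#' @export
adversarial_prob <- function(truth, concentration = 1) {
  truth <- as.factor(truth)
  K <- nlevels(truth)
  p <- matrix((1 - concentration) / K, length(truth), K,
              dimnames = list(NULL, levels(truth)))
  wrong <- K + 1L - as.integer(truth)
  p[cbind(seq_along(truth), wrong)] <- p[cbind(seq_along(truth), wrong)] + concentration
  p
}

#' Pruning benchmark with a planted adversarial member
#'
#' Adds an adversarial fifth member to the four organ pipelines of a
#' [fusion_benchmark()] run and prunes the soft-voting ensemble greedily
#' on internal-validation accuracy; the check is whether exactly the
#' adversarial member is removed.
#'
#' @param bench A [fusion_benchmark()] result.
#' @return list: `active_members`, `removed_only_adversary` (logical),
#'   `trajectory`.
#' @export
pruning_benchmark <- function(bench) {
  members <- c(names(bench$p_int), "adversary")
  probs <- bench$p_int
  adv <- adversarial_prob(bench$y_int)
  rownames(adv) <- rownames(probs[[1]])
  probs$adversary <- adv
  eval_fun <- function(subset) {
    mean(soft_vote(probs[subset])$predicted == bench$y_int)
  }
  res <- prune_ensemble(members, eval_fun)
  list(active_members = res$active_members,
       removed_only_adversary = setequal(res$active_members, names(bench$p_int)),
       trajectory = res$trajectory)
}
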