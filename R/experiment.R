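#' Experiment configuration
#'
#' Collects every tunable of the pipeline in one serializable object.
#' The defaults are the study's stated constants: 2 percent migration
#' tolerance, 5-of-6 replicate support, 70/30 rat-level split, the full
#' 4 x 5 selector/classifier grid, and the three combiners.
#'
#' @param design A [study_design()].
#' @param kinetics A [kinetics_params()].
#' @param tolerance Migration-matching tolerance.
#' @param min_support,replicates Replicate-support rule.
#' @param test_fraction Internal-validation fraction of rats.
#' @param selectors,classifiers,combiners Model grids.
#' @param include_single_organ_ensembles Run the selector-by-combiner
#'   single-organ ensemble grid (the costliest stage).
#' @param stacking_folds Folds for stacking meta-features.
#' @param seed Global seed; per-stage seeds are derived from it.
#' @return list of class `pmi_config`.
#' @export
experiment_config <- function(design = study_design(),
                              kinetics = kinetics_params(),
                              tolerance = 0.02,
                              min_support = 5L,
                              replicates = 6L,
                              test_fraction = 0.3,
                              selectors = pmi_selectors(),
                              classifiers = pmi_classifiers(),
                              combiners = c("stacking", "soft_voting",
                                            "soft_weighted_voting"),
                              include_single_organ_ensembles = TRUE,
                              stacking_folds = 5L,
                              seed = 1L) {
  structure(list(design = design, kinetics = kinetics, tolerance = tolerance,
                 min_support = as.integer(min_support),
                 replicates = as.integer(replicates),
                 test_fraction = test_fraction, selectors = selectors,
                 classifiers = classifiers, combiners = combiners,
                 include_single_organ_ensembles = include_single_organ_ensembles,
                 stacking_folds = as.integer(stacking_folds),
                 seed = as.integer(seed)),
            class = "pmi_config")
}

#' @keywords internal
#' Fixed per-stage seed derivation from the global seed.
stage_seed <- function(config, stage) {
  offs <- c(simulate = 0L, split = 1000L, search = 2000L, ensemble = 3000L,
            fusion = 4000L, prune = 5000L)
  config$seed + offs[[stage]]
}

#' Simulate and preprocess the study into per-organ modelling matrices
#'
#' Runs the data half of the workflow: simulate both cohorts, build the
#' fragment catalog from the training study (2 percent rule), apply the
#' replicate-support filter, split rats 70/30, assign external peaks to
#' the training catalog, build per-organ feature matrices and
#' standardize them on training statistics.
#'
#' @param config An [experiment_config()].
#' @return list: `catalog` (filtered study catalog), `split`, `study`
#'   (peaks + manifest), and `organs` — per organ a list with
#'   standardized `x_train`, `x_internal`, `x_external`, labels
#'   `y_train`, `y_internal`, `y_external` and rat-id vectors.
#' @export
prepare_study_data <- function(config) {
  # kinetics$seed fixes the underlying biology (fragment trajectories);
  # the experiment seed varies only rats, noise, dropout and the split.
  study <- simulate_study(config$design, load_reference_catalog(), config$kinetics,
                          noise_seed = stage_seed(config, "simulate"))
  man <- study$manifest
  man_train <- man[man$cohort == "training", ]
  peaks_train <- study$peaks[study$peaks$sample_id %in% man_train$sample_id, ]
  peaks_ext <- study$peaks[!study$peaks$sample_id %in% man_train$sample_id, ]

  catalog <- build_study_catalog(peaks_train, man_train, config$tolerance)
  catalog <- filter_by_replicate_support(catalog, man,
                                         min_support = config$min_support,
                                         replicates = config$replicates)
  split <- split_cohort(man, config$test_fraction, stage_seed(config, "split"))
  ext_assigned <- assign_to_catalog(peaks_ext, catalog,
                                    man[man$cohort == "external", ],
                                    config$tolerance)

  day_levels <- sort(unique(man$pmi_day))
  organs <- list()
  for (organ in config$design$organs) {
    fm_tr_all <- build_feature_matrix(catalog, man_train, organ)
    fm_ext <- build_feature_matrix(catalog, man[man$cohort == "external", ],
                                   organ, peaks = ext_assigned)
    rat_of <- fm_tr_all$meta$rat_id
    in_test <- rat_of %in% split$rat_id[split$split == "internal_test"]
    sub_fm <- function(keep) {
      structure(list(x = fm_tr_all$x[keep, , drop = FALSE],
                     label = fm_tr_all$label[keep],
                     meta = fm_tr_all$meta[keep, , drop = FALSE]),
                class = "feature_matrix")
    }
    fm_tr <- sub_fm(!in_test); fm_int <- sub_fm(in_test)
    std <- standardize_features(fm_tr, list(internal = fm_int, external = fm_ext))
    organs[[organ]] <- list(
      x_train = std$train$x, y_train = std$train$label,
      rat_train = std$train$meta$rat_id,
      x_internal = std$others$internal$x, y_internal = std$others$internal$label,
      rat_internal = std$others$internal$meta$rat_id,
      x_external = std$others$external$x, y_external = std$others$external$label,
      rat_external = std$others$external$meta$rat_id,
      center = std$center, scale = std$scale)
  }
  list(catalog = catalog, split = split, study = study, organs = organs,
       day_levels = day_levels)
}

#' @keywords internal
#' Per-organ probability matrix keyed by rat id.
organ_prob_by_rat <- function(pipeline, x, rats) {
  pr <- predict_proba(pipeline$model, x)
  rownames(pr) <- rats
  pr[order(rats), , drop = FALSE]
}

#' Run the full experiment
#'
#' Orchestrates the three workflow stages: (1) simulate, match, filter
#' and split; (2) per-organ sub-model search (selector x classifier
#' grid), rank-sum scoring and, optionally, the single-organ ensemble
#' grid; (3) multi-organ fusion of the per-organ best pipelines by the
#' three combiners, rank-sum choice of the best combiner, and greedy
#' ensemble pruning on internal-validation accuracy. Reruns with an
#' identical config reproduce identical outputs.
#'
#' @param config An [experiment_config()].
#' @param outdir Optional directory; when given, all tables are written
#'   as CSV/JSON artifacts.
#' @return list: `data`, `records` (80-row sub-model table), `ranks`,
#'   `best` (per-organ best model id), `ensembles` (single-organ
#'   ensemble records, if run), `fusion` (per-combiner metrics +
#'   predictions), `pruning`, `summary` (one row per organ best
#'   sub-model/ensemble and per multi-organ combiner).
#' @export
run_experiment <- function(config, outdir = NULL) {
  data <- prepare_study_data(config)
  organs <- config$design$organs
  search_seed <- stage_seed(config, "search")

  records <- do.call(rbind, lapply(organs, function(organ) {
    d <- data$organs[[organ]]
    run_cross_combination(d$x_train, d$y_train, d$x_internal, d$y_internal,
                          d$x_external, d$y_external, organ = organ,
                          seed = search_seed,
                          selectors = config$selectors,
                          classifiers = config$classifiers)
  }))
  if (any(!is.na(records$error))) {
    warning("sub-model failure(s): ",
            paste(unique(records$error[!is.na(records$error)]), collapse = "; "))
  }

  ranks <- lapply(organs, function(organ) {
    rank_models(records[records$organ == organ & is.na(records$error), ])
  })
  names(ranks) <- organs
  best <- vapply(organs, function(organ) {
    select_best(ranks[[organ]], records[records$organ == organ, ])
  }, character(1))

  ensembles <- NULL
  if (isTRUE(config$include_single_organ_ensembles)) {
    ensembles <- do.call(rbind, lapply(organs, function(organ) {
      d <- data$organs[[organ]]
      single_organ_ensembles(d$x_train, d$y_train, d$x_internal, d$y_internal,
                             d$x_external, d$y_external, organ = organ,
                             seed = stage_seed(config, "ensemble"),
                             selectors = config$selectors,
                             folds = config$stacking_folds)
    }))
  }

  # --- multi-organ fusion of the per-organ best pipelines -------------------
  fus_seed <- stage_seed(config, "fusion")
  pipes <- list(); p_int <- list(); p_ext <- list()
  xsel_train <- list(); xsel_int <- list(); xsel_ext <- list()
  w_int <- numeric(0)
  y_by_rat <- function(d, which) {
    y <- d[[paste0("y_", which)]]; r <- d[[paste0("rat_", which)]]
    y[order(r)]
  }
  for (organ in organs) {
    d <- data$organs[[organ]]
    sel_clf <- strsplit(best[[organ]], "+", fixed = TRUE)[[1]]
    pl <- fit_pipeline(sel_clf[1], sel_clf[2], d$x_train, d$y_train,
                       seed = search_seed)
    pipes[[organ]] <- pl
    p_int[[organ]] <- organ_prob_by_rat(pl, d$x_internal, d$rat_internal)
    p_ext[[organ]] <- organ_prob_by_rat(pl, d$x_external, d$rat_external)
    xsel_train[[organ]] <- {
      x <- d$x_train[order(d$rat_train), pl$features, drop = FALSE]
      rownames(x) <- sort(d$rat_train); x
    }
    xsel_int[[organ]] <- {
      x <- d$x_internal[order(d$rat_internal), pl$features, drop = FALSE]
      rownames(x) <- sort(d$rat_internal); x
    }
    xsel_ext[[organ]] <- {
      x <- d$x_external[order(d$rat_external), pl$features, drop = FALSE]
      rownames(x) <- sort(d$rat_external); x
    }
    w_int[organ] <- unname(evaluate_predictions(p_int[[organ]],
                                                y_by_rat(d, "internal"))["accuracy"])
  }
  d1 <- data$organs[[organs[1]]]
  y_tr <- y_by_rat(d1, "train"); y_int <- y_by_rat(d1, "internal")
  y_ext <- y_by_rat(d1, "external")

  stack <- NULL
  fusion <- list()
  for (cmb in config$combiners) {
    if (cmb == "stacking") {
      fit_funs <- lapply(organs, function(o) {
        clf <- pipes[[o]]$classifier
        function(x, y, s) train_classifier(clf, x, y, seed = s)
      })
      stack <- fit_stacking(xsel_train, y_tr, fit_funs,
                            folds = config$stacking_folds, seed = fus_seed)
      f_int <- predict_stacking(stack, xsel_int)
      f_ext <- predict_stacking(stack, xsel_ext)
    } else {
      w <- if (cmb == "soft_weighted_voting") w_int[organs] else NULL
      f_int <- fuse_organs(p_int, cmb, weights = w)
      f_ext <- fuse_organs(p_ext, cmb, weights = w)
    }
    fusion[[cmb]] <- list(
      internal = f_int, external = f_ext,
      metrics_internal = evaluate_predictions(f_int$prob, y_int),
      metrics_external = evaluate_predictions(f_ext$prob, y_ext),
      confusion_external = report_confusion(f_ext$predicted, y_ext))
  }
  fus_records <- do.call(rbind, lapply(names(fusion), function(cmb) {
    mi <- fusion[[cmb]]$metrics_internal; me <- fusion[[cmb]]$metrics_external
    data.frame(model = cmb,
               accuracy_internal = mi["accuracy"], precision_internal = mi["precision"],
               recall_internal = mi["recall"], auc_internal = mi["auc"],
               accuracy_external = me["accuracy"], precision_external = me["precision"],
               recall_external = me["recall"], auc_external = me["auc"],
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  best_combiner <- select_best(rank_models(fus_records), fus_records)

  # --- greedy pruning of the best multi-organ ensemble ----------------------
  eval_subset <- function(members) {
    members <- as.character(members)
    if (best_combiner == "stacking" && length(members) >= 2) {
      fit_funs <- lapply(members, function(o) {
        clf <- pipes[[o]]$classifier
        function(x, y, s) train_classifier(clf, x, y, seed = s)
      })
      st <- fit_stacking(xsel_train[members], y_tr, fit_funs,
                         folds = config$stacking_folds, seed = fus_seed)
      pred <- predict_stacking(st, xsel_int[members])$predicted
    } else {
      w <- if (best_combiner == "soft_weighted_voting") w_int[members] else
        rep(1, length(members))
      if (sum(w) == 0) w <- rep(1, length(members))
      pred <- soft_weighted_vote(p_int[members], w)$predicted
    }
    mean(pred == y_int)
  }
  pruning <- prune_ensemble(organs, eval_subset)

  summary <- build_summary(records, ranks, best, ensembles, fus_records, organs)
  bundle <- list(config = config, data = data, records = records, ranks = ranks,
                 best = best, ensembles = ensembles, fusion = fusion,
                 fusion_records = fus_records, best_combiner = best_combiner,
                 pruning = pruning, summary = summary)
  if (!is.null(outdir)) write_bundle(bundle, outdir)
  bundle
}

#' @keywords internal
build_summary <- function(records, ranks, best, ensembles, fus_records, organs) {
  rows <- list()
  for (organ in organs) {
    r <- records[records$organ == organ, ]
    id <- paste(r$selector, r$classifier, sep = "+")
    b <- r[id == best[[organ]], ]
    rows[[paste0(organ, "_submodel")]] <- data.frame(
      organ = organ, model = best[[organ]], kind = "sub_model",
      b[, grep("_(internal|external)$", names(b))], row.names = NULL)
    if (!is.null(ensembles)) {
      e <- ensembles[ensembles$organ == organ, ]
      e$model <- paste(e$selector, e$combiner, sep = "+")
      eb <- select_best(rank_models(e), e)
      eb_row <- e[e$model == eb, ]
      rows[[paste0(organ, "_ensemble")]] <- data.frame(
        organ = organ, model = eb, kind = "single_organ_ensemble",
        eb_row[, grep("_(internal|external)$", names(eb_row))], row.names = NULL)
    }
  }
  for (i in seq_len(nrow(fus_records))) {
    rows[[paste0("fusion_", fus_records$model[i])]] <- data.frame(
      organ = "multi_organ", model = fus_records$model[i], kind = "fusion",
      fus_records[i, grep("_(internal|external)$", names(fus_records))],
      row.names = NULL)
  }
  do.call(rbind, rows)
}

#' @keywords internal
write_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) utils::write.csv(df, file.path(outdir, name), row.names = FALSE)
  rec <- bundle$records
  rec$features <- vapply(rec$features, paste, character(1), collapse = ";")
  w(rec, "submodel_records.csv")
  rank_tab <- do.call(rbind, lapply(names(bundle$ranks), function(o) {
    data.frame(organ = o, bundle$ranks[[o]][, c("model", "total")], row.names = NULL)
  }))
  w(rank_tab, "rank_scores.csv")
  if (!is.null(bundle$ensembles)) w(bundle$ensembles, "single_organ_ensembles.csv")
  w(bundle$fusion_records, "fusion_records.csv")
  w(bundle$summary, "summary.csv")
  w(bundle$pruning$trajectory, "pruning_trajectory.csv")
  cat_df <- bundle$data$catalog$fragments
  cat_df$organs <- vapply(cat_df$organs, paste, character(1), collapse = ";")
  w(cat_df, "fragment_catalog.csv")
  for (cmb in names(bundle$fusion)) {
    cm <- as.data.frame.matrix(bundle$fusion[[cmb]]$confusion_external$matrix)
    utils::write.csv(cm, file.path(outdir, paste0("confusion_external_", cmb, ".csv")))
  }
  jsonlite::write_json(
    list(best = as.list(bundle$best), best_combiner = bundle$best_combiner,
         active_members = bundle$pruning$active_members,
         seed = bundle$config$seed),
    file.path(outdir, "experiment.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(outdir)
}
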