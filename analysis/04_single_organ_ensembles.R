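#!/usr/bin/env Rscript
# Stage 4: single-organ ensembles. For each organ and each selector, the
# five base classifiers are combined by stacking, soft voting and
# soft-weighted voting (weights = member internal-validation accuracy),
# and the best ensemble per organ is picked by the rank-sum score.
# The slowest stage (stacking refits every member per fold).

suppressMessages(library(pmifusion))
dir.create("results", showWarnings = FALSE)

cfg <- experiment_config(seed = 1L)
data <- suppressMessages(prepare_study_data(cfg))

ens <- do.call(rbind, lapply(pmi_organs(), function(organ) {
  message("ensembling ", organ, " ...")
  d <- data$organs[[organ]]
  suppressWarnings(single_organ_ensembles(
    d$x_train, d$y_train, d$x_internal, d$y_internal,
    d$x_external, d$y_external, organ = organ,
    seed = pmifusion:::stage_seed(cfg, "ensemble"),
    folds = cfg$stacking_folds))
}))
write.csv(ens, "results/single_organ_ensembles.csv", row.names = FALSE)

cat("\nbest ensemble per organ (rank-sum over the 12-cell grid):\n")
for (organ in pmi_organs()) {
  e <- ens[ens$organ == organ, ]
  e$model <- paste(e$selector, e$combiner, sep = "+")
  b <- select_best(rank_models(e), e)
  row <- e[e$model == b, ]
  cat(sprintf("  %-7s %-28s acc %.3f / %.3f\n", organ, b,
              row$accuracy_internal, row$accuracy_external))
}
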