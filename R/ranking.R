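#' Rank-sum scoring of candidate models
#'
#' Within each of the eight metric columns (accuracy, precision, recall,
#' AUC, each for internal and external validation) the M models are
#' ranked from worst to best: the best value scores M, the worst 1, and
#' ties share the average of their tied positions (which is what
#' produces half-integer totals). A model's total score is the sum of
#' its eight column scores; higher is better.
#'
#' @param records data.frame of evaluation records with a model
#'   identifier column (`model`, or `selector` + `classifier` pasted)
#'   and the eight metric columns named `accuracy_internal`, ...,
#'   `auc_external`.
#' @return data.frame: model, the eight per-column scores
#'   (`score_<metric>`), and `total`; ordered by decreasing total.
#' @export
rank_models <- function(records) {
  stopifnot(nrow(records) >= 1)
  metric_cols <- paste0(rep(c("accuracy", "precision", "recall", "auc"), 2),
                        rep(c("_internal", "_external"), each = 4))
  missing_cols <- setdiff(metric_cols, names(records))
  if (length(missing_cols)) stop("missing metric column(s): ",
                                 paste(missing_cols, collapse = ", "))
  model <- if ("model" %in% names(records)) records$model else
    paste(records$selector, records$classifier, sep = "+")
  for (mc in metric_cols) {
    bad <- !is.finite(records[[mc]])
    if (any(bad)) stop("missing metric ", mc, " for model(s): ",
                       paste(model[bad], collapse = ", "))
  }
  scores <- vapply(metric_cols, function(mc) {
    rank(records[[mc]], ties.method = "average")  # best value -> score M
  }, numeric(nrow(records)))
  scores <- matrix(scores, nrow = nrow(records),
                   dimnames = list(NULL, paste0("score_", metric_cols)))
  out <- data.frame(model = model, scores, total = rowSums(scores),
                    stringsAsFactors = FALSE)
  out[order(-out$total, out$model), ]
}

#' Pick the best model from a rank table
#'
#' Maximum total rank-sum score; ties are broken by higher external
#' accuracy, then lexicographically by model id (tie-breaks logged).
#'
#' @param table A [rank_models()] result.
#' @param records The original records (needed for the external-accuracy
#'   tie-break; optional when totals are unique).
#' @return The winning model identifier (character scalar).
#' @export
select_best <- function(table, records = NULL) {
  stopifnot(nrow(table) >= 1)
  top <- table$model[table$total == max(table$total)]
  if (length(top) > 1) {
    if (!is.null(records)) {
      model <- if ("model" %in% names(records)) records$model else
        paste(records$selector, records$classifier, sep = "+")
      ext <- records$accuracy_external[match(top, model)]
      top <- top[ext == max(ext)]
    }
    top <- sort(top)
    message("rank-score tie at the top broken in favour of ", top[1])
  }
  top[1]
}
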