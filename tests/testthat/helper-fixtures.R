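# Shared fixtures: all synthetic, built in code at test time.

tiny_design <- function(days = c(0, 7, 15, 30), rats = 6L, ext = 2L) {
  study_design(pmi_days = days, rats_per_timepoint = rats,
               external_rats_per_timepoint = ext)
}

noiseless_kinetics <- function(seed = 11L) {
  kinetics_params(noise_sigma = 0, jitter_sigma = 0, detection_threshold = 0,
                  seed = seed)
}

# Linearly separable toy classification data with a staircase mean design:
# informative feature j separates classes <= j from classes > j, so the
# full class identity needs all informative features; the rest is noise.
separable_data <- function(n_per_class = 10, classes = 3, p = 5,
                           informative = 2, sep = 6, seed = 1) {
  set.seed(seed)
  y <- factor(rep(seq_len(classes), each = n_per_class))
  x <- matrix(rnorm(length(y) * p), ncol = p,
              dimnames = list(NULL, paste0("F", seq_len(p))))
  for (k in seq_len(classes)) {
    rows <- y == levels(y)[k]
    for (j in seq_len(informative)) {
      x[rows, j] <- x[rows, j] + sep * (k > j)
    }
  }
  x <- scale(x)
  attr(x, "scaled:center") <- NULL
  attr(x, "scaled:scale") <- NULL
  list(x = x, y = y)
}

# Random eight-column metric table for rank-scoring checks.
random_metric_table <- function(M, seed = 1, round_to = NULL) {
  set.seed(seed)
  cols <- paste0(rep(c("accuracy", "precision", "recall", "auc"), 2),
                 rep(c("_internal", "_external"), each = 4))
  d <- as.data.frame(matrix(runif(M * 8), nrow = M, dimnames = list(NULL, cols)))
  if (!is.null(round_to)) d[] <- lapply(d, round, digits = round_to)
  d$model <- paste0("m", seq_len(M))
  d
}

# Confident, mostly-correct probability matrix for ensemble tests.
informative_prob <- function(truth, confidence = 0.7, seed = 1) {
  set.seed(seed)
  truth <- as.factor(truth)
  K <- nlevels(truth)
  p <- matrix(stats::runif(length(truth) * K, 0, 0.2), ncol = K,
              dimnames = list(NULL, levels(truth)))
  p[cbind(seq_along(truth), as.integer(truth))] <-
    p[cbind(seq_along(truth), as.integer(truth))] + confidence
  p / rowSums(p)
}
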