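#' Study design of the rat decomposition time course
#'
#' The default values reproduce the study design the pipeline assumes:
#' organs are sampled from rats sacrificed at 14 fixed post-mortem time
#' points (days 0--30), six rats per time point in the training study
#' (84 rats, 336 organ samples) and two rats per time point in an
#' independent external-validation cohort (28 rats).
#'
#' @param pmi_days Ordered vector of post-mortem days.
#' @param rats_per_timepoint Training-study rats per time point.
#' @param external_rats_per_timepoint External-cohort rats per time point.
#' @param organs Organ labels harvested from every rat.
#' @return A list of class `pmi_design`.
#' @export
study_design <- function(pmi_days = c(0, 1, 2, 3, 5, 7, 9, 12, 15, 18, 21, 24, 27, 30),
                         rats_per_timepoint = 6L,
                         external_rats_per_timepoint = 2L,
                         organs = pmi_organs()) {
  if (length(pmi_days) == 0 || rats_per_timepoint < 1 || length(organs) == 0) {
    stop("empty study design")
  }
  if (is.unsorted(pmi_days, strictly = TRUE)) stop("pmi_days must be strictly increasing")
  structure(list(pmi_days = as.numeric(pmi_days),
                 rats_per_timepoint = as.integer(rats_per_timepoint),
                 external_rats_per_timepoint = as.integer(external_rats_per_timepoint),
                 organs = organs),
            class = "pmi_design")
}

#' Degradation-kinetics and noise parameters for the simulator
#'
#' Each fragment follows a rise-then-decay trajectory in time: its peak
#' height climbs exponentially towards a fragment-specific peak day (new
#' degradation products accumulating) and decays exponentially afterwards
#' (further proteolysis), so the vector of fragment heights separates the
#' PMI classes. Replicate-to-replicate variation is multiplicative
#' lognormal (heights are positive fluorescence intensities), migration
#' times jitter by a small relative Gaussian factor, and peaks below the
#' detection threshold are dropped. Organ noise multipliers scale the
#' replicate noise per organ, emulating organs that degrade more or less
#' reproducibly.
#'
#' @param baseline_meanlog,baseline_sdlog Lognormal parameters of the
#'   fragment peak-day height (fluorescence units).
#' @param peak_day_range Range (days) the per-fragment peak day is drawn from.
#' @param rise_range,decay_range Ranges (per day) of the exponential rise
#'   and decay rates.
#' @param noise_sigma Lognormal sigma of replicate noise.
#' @param jitter_sigma Relative migration-time jitter SD; the default 0.004
#'   keeps within-fragment deviations well below the 2 percent matching
#'   tolerance.
#' @param detection_threshold Minimum height (fluorescence units) for a
#'   peak to be reported.
#' @param organ_noise Named per-organ multipliers of `noise_sigma`.
#' @param seed Integer seed controlling the per-fragment trajectory draw.
#' @return A list of class `pmi_kinetics`.
#' @export
kinetics_params <- function(baseline_meanlog = log(200),
                            baseline_sdlog = 0.5,
                            peak_day_range = c(0, 30),
                            rise_range = c(0.08, 0.35),
                            decay_range = c(0.08, 0.35),
                            noise_sigma = 0.35,
                            jitter_sigma = 0.004,
                            detection_threshold = 5,
                            organ_noise = c(lung = 1.05, liver = 1.2,
                                            kidney = 0.7, muscle = 0.85),
                            seed = 1L) {
  stopifnot(noise_sigma >= 0, jitter_sigma >= 0, detection_threshold >= 0,
            all(organ_noise > 0))
  structure(list(baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 peak_day_range = peak_day_range,
                 rise_range = rise_range,
                 decay_range = decay_range,
                 noise_sigma = noise_sigma,
                 jitter_sigma = jitter_sigma,
                 detection_threshold = detection_threshold,
                 organ_noise = organ_noise,
                 seed = as.integer(seed)),
            class = "pmi_kinetics")
}

#' Draw per-fragment, per-organ trajectory parameters
#'
#' One trajectory is drawn for every (fragment, organ) membership pair:
#' post-mortem degradation dynamics are organ-specific (the same
#' polypeptide may accumulate early in one organ and late in another),
#' which is what makes the four organs complementary views of the PMI.
#' Deterministic given `kinetics$seed`, so the training and external
#' cohorts share one underlying biology.
#'
#' @param catalog Reference catalog (see [load_reference_catalog()]).
#' @param kinetics A [kinetics_params()] object.
#' @return data.frame: fragment_id, organ, amplitude, peak_day, rise, decay.
#' @export
draw_fragment_kinetics <- function(catalog, kinetics) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(kinetics$seed)
  pairs <- data.frame(
    fragment_id = rep(catalog$fragment_id, lengths(catalog$organs)),
    organ = unlist(catalog$organs))
  n <- nrow(pairs)
  pairs$amplitude <- exp(stats::rnorm(n, kinetics$baseline_meanlog,
                                      kinetics$baseline_sdlog))
  pairs$peak_day <- stats::runif(n, kinetics$peak_day_range[1],
                                 kinetics$peak_day_range[2])
  pairs$rise <- stats::runif(n, kinetics$rise_range[1], kinetics$rise_range[2])
  pairs$decay <- stats::runif(n, kinetics$decay_range[1], kinetics$decay_range[2])
  pairs
}

#' @keywords internal
fragment_trajectory <- function(day, traj) {
  ifelse(day < traj$peak_day,
         traj$amplitude * exp(-traj$rise * (traj$peak_day - day)),
         traj$amplitude * exp(-traj$decay * (day - traj$peak_day)))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Simulate one cohort of lab-on-chip peak tables
#'
#' Emits, for every rat and organ, the list of detected electropherogram
#' peaks: a fragment appears only in organs of its membership set, its
#' observed height is the trajectory value at the rat's PMI day times a
#' lognormal replicate factor (scaled per organ), and its migration time
#' is the catalog mean times `1 + N(0, jitter_sigma)`. Peaks whose height
#' falls below the detection threshold are dropped. Identical arguments
#' (including seeds) yield identical tables.
#'
#' @param design A [study_design()].
#' @param catalog Reference catalog.
#' @param kinetics A [kinetics_params()]; `kinetics$seed` fixes the
#'   fragment trajectories.
#' @param cohort `"training"` or `"external"`; the external cohort uses
#'   `external_rats_per_timepoint` and its own rat ids.
#' @param noise_seed Seed for the replicate/jitter noise stream (defaults
#'   to a fixed offset of `kinetics$seed`, distinct per cohort).
#' @return list(peaks = data.frame(sample_id, migration_time_s,
#'   molecular_mass_kda, peak_height), manifest = data.frame(sample_id,
#'   rat_id, organ, pmi_day, cohort)).
#' @export
simulate_cohort <- function(design, catalog, kinetics,
                            cohort = c("training", "external"),
                            noise_seed = NULL) {
  cohort <- match.arg(cohort)
  if (!inherits(design, "pmi_design")) stop("design must be a pmi_design")
  if (kinetics$jitter_sigma >= 0.01) {
    warning("jitter_sigma >= 0.01 risks violating the 2% migration-time matching assumption")
  }
  n_rats_tp <- if (cohort == "training") design$rats_per_timepoint else design$external_rats_per_timepoint
  if (n_rats_tp < 1) stop("cohort has no rats")
  prefix <- if (cohort == "training") "R" else "E"
  if (is.null(noise_seed)) {
    noise_seed <- kinetics$seed + if (cohort == "training") 10000L else 20000L
  }
  traj <- draw_fragment_kinetics(catalog, kinetics)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(noise_seed)

  rat_days <- rep(design$pmi_days, each = n_rats_tp)
  man_rows <- list()
  peak_rows <- list()
  k <- 0L
  for (ri in seq_along(rat_days)) {
    rat_id <- sprintf("%s%03d", prefix, ri)
    day <- rat_days[ri]
    for (organ in design$organs) {
      sample_id <- paste0(rat_id, "_", organ)
      tro <- traj[traj$organ == organ, , drop = FALSE]
      idx <- match(tro$fragment_id, catalog$fragment_id)
      mu <- fragment_trajectory(day, tro)
      sig <- kinetics$noise_sigma * kinetics$organ_noise[[organ]]
      h <- mu * exp(stats::rnorm(length(idx), 0, sig))
      mig <- catalog$mean_migration[idx] *
        (1 + stats::rnorm(length(idx), 0, kinetics$jitter_sigma))
      mass <- catalog$mean_mass[idx] *
        (1 + stats::rnorm(length(idx), 0, 2 * kinetics$jitter_sigma))
      keep <- h >= kinetics$detection_threshold
      k <- k + 1L
      man_rows[[k]] <- data.frame(sample_id = sample_id, rat_id = rat_id,
                                  organ = organ, pmi_day = day,
                                  cohort = cohort, stringsAsFactors = FALSE)
      if (any(keep)) {
        peak_rows[[k]] <- data.frame(sample_id = sample_id,
                                     migration_time_s = mig[keep],
                                     molecular_mass_kda = mass[keep],
                                     peak_height = h[keep],
                                     stringsAsFactors = FALSE)
      }
    }
  }
  list(peaks = do.call(rbind, peak_rows),
       manifest = do.call(rbind, man_rows))
}

#' Simulate the full study (training plus external cohort)
#'
#' @inheritParams simulate_cohort
#' @param noise_seed Base seed of the measurement-noise streams (rat
#'   draws, jitter, dropout); defaults to `kinetics$seed`. Varying it
#'   while keeping `kinetics$seed` fixed replicates the experiment under
#'   one underlying biology.
#' @return list(peaks, manifest) with both cohorts stacked; the external
#'   cohort shares the fragment trajectories but uses a fresh noise stream.
#' @export
simulate_study <- function(design, catalog, kinetics, noise_seed = kinetics$seed) {
  tr <- simulate_cohort(design, catalog, kinetics, "training",
                        noise_seed = noise_seed + 10000L)
  ex <- simulate_cohort(design, catalog, kinetics, "external",
                        noise_seed = noise_seed + 20000L)
  list(peaks = rbind(tr$peaks, ex$peaks),
       manifest = rbind(tr$manifest, ex$manifest))
}

#' Split training rats into train and internal-test partitions
#'
#' The split is by rat (all four organ samples of a rat land on the same
#' side, so multi-organ fusion never trains and tests on the same animal)
#' and stratified by PMI class as evenly as the class sizes allow. The
#' internal-test size is `ceiling(test_fraction * n_rats)`.
#'
#' @param manifest Sample manifest; only rows with `cohort == "training"`
#'   are split.
#' @param test_fraction Proportion of rats held out (default 0.3).
#' @param seed Integer seed; identical seeds give identical partitions.
#' @return data.frame(rat_id, pmi_day, split) with split in
#'   `{"train", "internal_test"}`.
#' @export
split_cohort <- function(manifest, test_fraction = 0.3, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  rats <- unique(manifest[manifest$cohort == "training", c("rat_id", "pmi_day")])
  n <- nrow(rats)
  if (n < 2) stop("need at least two rats to split")
  n_test <- as.integer(ceiling(test_fraction * n))
  if (n_test >= n || n_test < 1) stop("split would leave an empty partition")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  days <- sort(unique(rats$pmi_day))
  K <- length(days)
  quota <- rep(n_test %/% K, K)
  rem <- n_test - sum(quota)
  if (rem > 0) {
    # one extra held-out slot for `rem` randomly chosen classes
    extra <- sample.int(K, rem)
    quota[extra] <- quota[extra] + 1L
  }
  sizes <- vapply(days, function(d) sum(rats$pmi_day == d), integer(1))
  # cap quotas at class size minus one would starve tiny classes; cap at size
  over <- pmax(quota - sizes, 0L)
  quota <- pmin(quota, sizes)
  spare <- which(quota < sizes)
  i <- 1L
  need <- sum(over)
  while (need > 0 && length(spare)) {
    d <- spare[(i - 1L) %% length(spare) + 1L]
    if (quota[d] < sizes[d]) {
      quota[d] <- quota[d] + 1L
      need <- need - 1L
    }
    i <- i + 1L
    spare <- which(quota < sizes)
  }
  test_rats <- unlist(lapply(seq_along(days), function(j) {
    pool <- rats$rat_id[rats$pmi_day == days[j]]
    if (quota[j] == 0L) return(character(0))
    pool[sample.int(length(pool), quota[j])]
  }))
  rats$split <- ifelse(rats$rat_id %in% test_rats, "internal_test", "train")
  if (!any(rats$split == "train")) stop("split left an empty training set")
  rats[order(rats$rat_id), c("rat_id", "pmi_day", "split")]
}
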