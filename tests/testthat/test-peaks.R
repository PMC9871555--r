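cat45 <- load_reference_catalog()

peak_df <- function(times, samples = NULL, heights = 100, masses = 50) {
  data.frame(sample_id = if (is.null(samples)) paste0("s", seq_along(times)) else samples,
             migration_time_s = times,
             molecular_mass_kda = rep_len(masses, length(times)),
             peak_height = rep_len(heights, length(times)))
}

partition_key <- function(assignment) {
  # canonical form for comparing partitions regardless of label values
  as.integer(factor(assignment, levels = unique(assignment)))
}

test_that("basic matching follows the 2% migration rule", {
  one <- match_fragments(peak_df(20.68))
  expect_equal(nrow(one$fragments), 1)
  # 20.68 vs 20.95 from different samples: 1.3% apart -> same fragment
  near <- match_fragments(peak_df(c(20.68, 20.95)))
  expect_equal(length(unique(near$assignment)), 1)
  # 20.68 vs 21.34: 3.2% apart -> distinct fragments
  far <- match_fragments(peak_df(c(20.68, 21.34)))
  expect_equal(length(unique(far$assignment)), 2)
  expect_error(match_fragments(peak_df(c(20, -1))), "positive")
})

test_that("co-detected peaks of one sample stay distinct fragments", {
  # both peaks in every sample, 1.3% apart: resolvable only via cannot-link
  pk <- peak_df(rep(c(20.68, 20.95), 3), samples = rep(paste0("s", 1:3), each = 2))
  res <- match_fragments(pk)
  expect_equal(nrow(res$fragments), 2)
  expect_equal(res$fragments$mean_migration, c(20.68, 20.95))
})

test_that("greedy matcher equals the exhaustive oracle on separated instances", {
  for (s in 1:30) {
    inst <- random_peak_instance(n = sample(5:30, 1), k = sample(2:6, 1), seed = s)
    res <- match_fragments(peak_df(inst$times))
    expect_equal(partition_key(res$assignment),
                 partition_key(cluster_oracle(inst$times)),
                 info = paste("instance seed", s))
    expect_equal(partition_key(res$assignment), partition_key(inst$truth))
  }
})

test_that("input order does not change partitions of separated clusters", {
  inst <- random_peak_instance(n = 24, k = 4, seed = 42)
  base <- match_fragments(peak_df(inst$times))
  set.seed(1)
  for (i in 1:5) {
    perm <- sample(length(inst$times))
    res <- match_fragments(peak_df(inst$times[perm]))
    expect_equal(partition_key(res$assignment[order(perm)]),
                 partition_key(base$assignment))
  }
})

test_that("assigned peaks respect the tolerance against final fragment means", {
  st <- simulate_cohort(tiny_design(), cat45, kinetics_params(seed = 4), "training")
  man <- st$manifest
  kid <- st$peaks[st$peaks$sample_id %in% man$sample_id[man$organ == "kidney"], ]
  res <- match_fragments(kid)
  dev <- abs(res$peaks$migration_time_s -
               res$fragments$mean_migration[res$peaks$fragment_id]) /
    res$fragments$mean_migration[res$peaks$fragment_id]
  expect_true(all(dev < 0.02))
})

test_that("replicate-support filter keeps >=5/6 fragments and drops the rest", {
  # synthetic toy: organ 'lung', 6 rats at day 0; fragment A in all six,
  # fragment B in four rats only at every time point
  rats <- paste0("R", 1:6)
  man <- data.frame(sample_id = paste0(rats, "_lung"), rat_id = rats,
                    organ = "lung", pmi_day = 0, cohort = "training")
  pk <- rbind(peak_df(rep(20, 6), samples = man$sample_id),
              peak_df(rep(30, 4), samples = man$sample_id[1:4]))
  sc <- build_study_catalog(pk, man)
  expect_equal(nrow(sc$fragments), 2)
  filt <- filter_by_replicate_support(sc, man, min_support = 5)
  expect_equal(nrow(filt$fragments), 1)
  expect_equal(filt$fragments$mean_migration, 20)
  # peaks of the removed fragment become unassigned
  expect_true(anyNA(filt$peaks$fragment_id))
})

test_that("no fragment is removed from a zero-noise full-support cohort", {
  st <- simulate_cohort(study_design(), cat45, noiseless_kinetics(), "training")
  sc <- build_study_catalog(st$peaks, st$manifest)
  filt <- filter_by_replicate_support(sc, st$manifest)
  expect_equal(nrow(filt$fragments), nrow(sc$fragments))
})

test_that("undersized replicate groups are skipped with a warning", {
  rats <- paste0("R", 1:3)
  man <- data.frame(sample_id = paste0(rats, "_lung"), rat_id = rats,
                    organ = "lung", pmi_day = 0, cohort = "training")
  pk <- peak_df(rep(20, 3), samples = man$sample_id)
  sc <- build_study_catalog(pk, man)
  expect_warning(filter_by_replicate_support(sc, man, min_support = 5),
                 "skipped")
})

test_that("zero-noise cohorts recover the reference catalog exactly", {
  st <- simulate_cohort(study_design(), cat45, noiseless_kinetics(), "training")
  sc <- build_study_catalog(st$peaks, st$manifest)
  expect_equal(nrow(sc$fragments), 45)
  for (i in seq_len(45)) {
    expect_setequal(sc$fragments$organs[[i]], cat45$organs[[i]])
  }
  expect_equal(sc$fragments$mean_migration, cat45$mean_migration, tolerance = 1e-8)
})

test_that("feature matrices fill, deduplicate and error as specified", {
  st <- simulate_cohort(study_design(), cat45, noiseless_kinetics(), "training")
  sc <- build_study_catalog(st$peaks, st$manifest)
  sc <- filter_by_replicate_support(sc, st$manifest)
  fm <- build_feature_matrix(sc, st$manifest, "kidney")
  expect_equal(dim(fm$x), c(84, 19))  # 84 kidney samples x 19 kidney fragments
  expect_false(anyNA(fm$x))

  # explicit duplicate assignment: keep the taller peak
  rats <- paste0("R", 1:6)
  man <- data.frame(sample_id = paste0(rats, "_lung"), rat_id = rats,
                    organ = "lung", pmi_day = 0, cohort = "training")
  pk <- peak_df(rep(20, 6), samples = man$sample_id)
  sc2 <- build_study_catalog(pk, man)
  dup <- sc2$peaks[1, ]; dup$peak_height <- 250
  sc2$peaks$peak_height[1] <- 10
  sc2$peaks <- rbind(sc2$peaks, dup)
  fm2 <- suppressMessages(build_feature_matrix(sc2, man, "lung"))
  expect_equal(unname(fm2$x[dup$sample_id, 1]), 250)

  man_extra <- rbind(man, data.frame(sample_id = "R9_lung", rat_id = "R9",
                                     organ = "lung", pmi_day = 0,
                                     cohort = "training"))
  expect_error(build_feature_matrix(sc2, man_extra, "lung"), "no peak table")
})

test_that("standardization is train-estimated, applied identically, invertible", {
  set.seed(1)
  tr <- matrix(rnorm(60, 10, 3), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  tr[, 3] <- 7  # constant column
  ext <- matrix(rnorm(30, 10, 3), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  std <- standardize_features(tr, list(ext = ext))
  expect_equal(unname(colMeans(std$train)[1:2]), c(0, 0))
  expect_equal(unname(apply(std$train, 2, sd)[1:2]), c(1, 1))
  expect_true(all(std$train[, 3] == 0))  # constant column centered to zero
  back <- sweep(sweep(std$others$ext, 2, std$scale, "*"), 2, std$center, "+")
  expect_equal(back, ext)
})

test_that("external peaks map onto the training catalog without new fragments", {
  des <- tiny_design()
  st <- simulate_study(des, cat45, noiseless_kinetics())
  man_tr <- st$manifest[st$manifest$cohort == "training", ]
  man_ex <- st$manifest[st$manifest$cohort == "external", ]
  pk_tr <- st$peaks[st$peaks$sample_id %in% man_tr$sample_id, ]
  pk_ex <- st$peaks[st$peaks$sample_id %in% man_ex$sample_id, ]
  sc <- filter_by_replicate_support(build_study_catalog(pk_tr, man_tr), st$manifest)
  asn <- assign_to_catalog(pk_ex, sc, man_ex)
  expect_true(all(asn$fragment_id %in% sc$fragments$fragment_id))
  # far-off peak is dropped with a message
  stray <- pk_ex[1, ]; stray$migration_time_s <- 60
  expect_message(assign_to_catalog(rbind(pk_ex, stray), sc, man_ex), "dropped")
})
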