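cat45 <- load_reference_catalog()

test_that("default design yields the full study layout", {
  st <- simulate_study(study_design(), cat45, noiseless_kinetics())
  man <- st$manifest
  expect_equal(sum(man$cohort == "training"), 84 * 4)   # 336 organ samples
  expect_equal(length(unique(man$rat_id[man$cohort == "training"])), 84)
  expect_equal(length(unique(man$rat_id[man$cohort == "external"])), 28)
  expect_equal(sort(unique(man$pmi_day)),
               c(0, 1, 2, 3, 5, 7, 9, 12, 15, 18, 21, 24, 27, 30))
})

test_that("zero noise makes biological replicates identical", {
  des <- tiny_design()
  st <- simulate_cohort(des, cat45, noiseless_kinetics(), "training")
  man <- st$manifest
  day0 <- man[man$pmi_day == 0 & man$organ == "kidney", "sample_id"]
  lists <- lapply(day0, function(s) {
    p <- st$peaks[st$peaks$sample_id == s, c("migration_time_s", "peak_height")]
    p[order(p$migration_time_s), ]
  })
  for (i in seq_along(lists)[-1]) {
    expect_equal(lists[[i]], lists[[1]], ignore_attr = TRUE)
  }
})

test_that("identical seeds give byte-identical peak tables", {
  kin <- kinetics_params(seed = 5)
  a <- simulate_cohort(tiny_design(), cat45, kin, "training", noise_seed = 99)
  b <- simulate_cohort(tiny_design(), cat45, kin, "training", noise_seed = 99)
  expect_identical(a, b)
  c2 <- simulate_cohort(tiny_design(), cat45, kin, "training", noise_seed = 100)
  expect_false(identical(a$peaks, c2$peaks))
})

test_that("raising the detection threshold never adds peaks", {
  thresholds <- c(0, 2, 5, 20, 100)
  counts <- vapply(thresholds, function(th) {
    kin <- kinetics_params(detection_threshold = th, seed = 3)
    nrow(simulate_cohort(tiny_design(), cat45, kin, "training", noise_seed = 7)$peaks)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("fragments appear only in organs of their membership set", {
  st <- simulate_cohort(tiny_design(), cat45, noiseless_kinetics(), "training")
  pk <- merge(st$peaks, st$manifest[, c("sample_id", "organ")], by = "sample_id")
  # zero jitter: migration times identify fragments exactly
  pk$fragment_id <- match(pk$migration_time_s, cat45$mean_migration)
  expect_false(anyNA(pk$fragment_id))
  obs <- tapply(pk$organ, pk$fragment_id, function(o) sort(unique(o)))
  for (fid in as.integer(names(obs))) {
    expect_setequal(obs[[as.character(fid)]], cat45$organs[[fid]])
  }
})

test_that("simulator validates its inputs", {
  expect_error(study_design(pmi_days = numeric(0)), "empty")
  expect_warning(
    simulate_cohort(tiny_design(), cat45, kinetics_params(jitter_sigma = 0.012),
                    "training"),
    "2%")
  expect_error(kinetics_params(noise_sigma = -1))
})

test_that("rat-level split has the right size, stratification and determinism", {
  st <- simulate_study(study_design(), cat45, noiseless_kinetics())
  sp <- split_cohort(st$manifest, 0.3, seed = 2)
  expect_equal(sum(sp$split == "internal_test"), 26)  # ceiling(0.3 * 84)
  expect_equal(sum(sp$split == "train"), 58)
  per_class <- table(sp$pmi_day[sp$split == "internal_test"])
  expect_true(all(per_class %in% 1:2))  # 26 over 14 classes: as even as possible
  expect_identical(sp, split_cohort(st$manifest, 0.3, seed = 2))
  expect_false(identical(sp, split_cohort(st$manifest, 0.3, seed = 3)))
})

test_that("split handles the smallest cohort and rejects empty partitions", {
  man <- data.frame(sample_id = c("R1_lung", "R2_lung"),
                    rat_id = c("R1", "R2"), organ = "lung",
                    pmi_day = 0, cohort = "training")
  sp <- split_cohort(man, 0.5, seed = 1)
  expect_equal(sum(sp$split == "internal_test"), 1)
  expect_equal(sum(sp$split == "train"), 1)
  expect_error(split_cohort(man, 0.99, seed = 1), "empty")
})
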