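#' Match electropherogram peaks into polypeptide fragments
#'
#' Greedy clustering on migration time: peaks are processed in ascending
#' migration order; each peak joins the existing fragment whose running
#' mean migration time is closest in relative terms, provided that
#' deviation is below `tolerance` (the instrument's fragment-identity
#' criterion: migration deviations under 2 percent denote the same
#' polypeptide). Otherwise the peak seeds a new fragment. Fragment ids
#' are re-assigned by ascending final mean migration time.
#'
#' Two peaks of one and the same sample are always distinct fragments
#' (a single electropherogram resolves them as separate peaks), so when
#' `peaks` carries a `sample_id` column a peak never joins a cluster
#' that already holds a peak of its own sample; it falls through to the
#' next-nearest admissible cluster or seeds a new one. This cannot-link
#' constraint is what lets true fragments closer than the tolerance
#' (which the reference catalog contains) stay separate.
#'
#' @param peaks data.frame with at least `migration_time_s`,
#'   `molecular_mass_kda`, `peak_height` (and usually `sample_id`).
#' @param tolerance Maximum relative migration-time deviation (default
#'   0.02); must lie in (0, 0.1).
#' @return list of class `fragment_catalog`: `fragments` (data.frame
#'   fragment_id, mean_mass, sd_mass, mean_migration, sd_migration,
#'   n_peaks), `assignment` (integer fragment_id per input peak row, in
#'   the input row order), and the `peaks` with an added `fragment_id`
#'   column.
#' @export
match_fragments <- function(peaks, tolerance = 0.02) {
  stopifnot(nrow(peaks) > 0, tolerance > 0, tolerance < 0.1)
  t <- peaks$migration_time_s
  if (any(!is.finite(t)) || any(t <= 0)) stop("migration times must be finite and positive")
  sid <- if ("sample_id" %in% names(peaks)) as.character(peaks$sample_id) else
    as.character(seq_along(t))  # all distinct: constraint never fires

  ord <- order(t)
  sums <- numeric(0); counts <- integer(0)
  members <- list()  # sample ids per cluster (cannot-link bookkeeping)
  cl <- integer(length(t))
  for (i in ord) {
    placed <- FALSE
    if (length(sums)) {
      means <- sums / counts
      dev <- abs(t[i] - means) / means
      for (j in order(dev)) {  # nearest admissible cluster
        if (dev[j] >= tolerance) break
        if (sid[i] %in% members[[j]]) next
        sums[j] <- sums[j] + t[i]; counts[j] <- counts[j] + 1L
        members[[j]] <- c(members[[j]], sid[i])
        cl[i] <- j
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      sums <- c(sums, t[i]); counts <- c(counts, 1L)
      members[[length(sums)]] <- sid[i]
      cl[i] <- length(sums)
    }
  }
  # renumber by ascending final mean migration time
  means <- sums / counts
  rk <- rank(means, ties.method = "first")
  cl <- rk[cl]

  frag_stats <- function(v, f) {
    data.frame(mean = tapply(v, f, mean), sd = tapply(v, f, function(x) {
      if (length(x) > 1) stats::sd(x) else 0
    }))
  }
  mg <- frag_stats(t, cl)
  ms <- frag_stats(peaks$molecular_mass_kda, cl)
  fragments <- data.frame(fragment_id = sort(unique(cl)),
                          mean_mass = ms$mean, sd_mass = ms$sd,
                          mean_migration = mg$mean, sd_migration = mg$sd,
                          n_peaks = as.integer(table(cl)))
  out_peaks <- peaks
  out_peaks$fragment_id <- cl
  structure(list(fragments = fragments, assignment = cl, peaks = out_peaks),
            class = "fragment_catalog")
}

#' Build a study-wide catalog from per-organ peak tables
#'
#' Matching is performed separately within each organ, then the organ
#' catalogs' mean migration times are themselves clustered with the same
#' tolerance to assign study-wide fragment numbers (ascending migration
#' time) and organ-membership sets, reproducing the cross-organ catalog
#' layout of the reference table.
#'
#' @param peaks Peak table with `sample_id`.
#' @param manifest Sample manifest mapping `sample_id` to `organ`.
#' @param tolerance Relative migration tolerance (default 0.02).
#' @return list of class `study_catalog`: `fragments` (fragment_id,
#'   mean_mass, sd_mass, mean_migration, sd_migration, organs
#'   list-column), `organ_catalogs` (per-organ `fragment_catalog` with a
#'   `study_id` column mapping local to study-wide ids), and `peaks`
#'   (all peaks with organ, study-wide fragment_id).
#' @export
build_study_catalog <- function(peaks, manifest, tolerance = 0.02) {
  organs <- intersect(pmi_organs(), unique(manifest$organ))
  organ_catalogs <- list()
  centroid_rows <- list()
  for (organ in organs) {
    sids <- manifest$sample_id[manifest$organ == organ]
    op <- peaks[peaks$sample_id %in% sids, , drop = FALSE]
    if (!nrow(op)) next
    oc <- match_fragments(op, tolerance)
    organ_catalogs[[organ]] <- oc
    f <- oc$fragments
    centroid_rows[[organ]] <- data.frame(organ = organ,
                                         local_id = f$fragment_id,
                                         migration_time_s = f$mean_migration,
                                         sd_migration = f$sd_migration,
                                         n_peaks = f$n_peaks,
                                         molecular_mass_kda = f$mean_mass,
                                         peak_height = 1)
  }
  cent <- do.call(rbind, centroid_rows)
  cent$study_id <- merge_organ_centroids(cent, tolerance)

  frag_ids <- sort(unique(cent$study_id))
  organs_per_frag <- lapply(frag_ids, function(fid) {
    unname(cent$organ[cent$study_id == fid])
  })
  # study-wide stats pooled over member peaks
  all_rows <- list()
  for (organ in names(organ_catalogs)) {
    oc <- organ_catalogs[[organ]]
    map <- cent$study_id[cent$organ == organ][match(oc$assignment,
                                                    cent$local_id[cent$organ == organ])]
    p <- oc$peaks
    p$organ <- organ
    p$fragment_id <- map
    organ_catalogs[[organ]]$study_id <- cent$study_id[cent$organ == organ][
      match(oc$fragments$fragment_id, cent$local_id[cent$organ == organ])]
    all_rows[[organ]] <- p
  }
  pooled <- do.call(rbind, all_rows)
  agg <- function(v) {
    m <- tapply(v, pooled$fragment_id, mean)
    s <- tapply(v, pooled$fragment_id, function(x) if (length(x) > 1) stats::sd(x) else 0)
    list(m = m, s = s)
  }
  mg <- agg(pooled$migration_time_s); ms <- agg(pooled$molecular_mass_kda)
  fragments <- data.frame(fragment_id = frag_ids,
                          mean_mass = as.numeric(ms$m), sd_mass = as.numeric(ms$s),
                          mean_migration = as.numeric(mg$m),
                          sd_migration = as.numeric(mg$s))
  fragments$organs <- organs_per_frag
  structure(list(fragments = fragments, organ_catalogs = organ_catalogs,
                 peaks = pooled),
            class = "study_catalog")
}

#' Merge per-organ fragment centroids into study-wide fragments
#'
#' Greedy clustering of organ-catalog centroids by ascending migration
#' time. A centroid joins an existing study fragment only if (a) its
#' relative migration deviation from the fragment's running mean is
#' below `tolerance`, (b) the fragment holds no centroid of the same
#' organ yet (one fragment has at most one centroid per organ), and (c)
#' the centroid means are statistically indistinguishable given the
#' within-fragment migration spread: the gap must lie within 3 combined
#' standard errors (exact equality required when the spreads are zero,
#' e.g. for jitter-free data). Study ids are renumbered by ascending
#' mean migration.
#'
#' @param cent data.frame: organ, migration_time_s, sd_migration, n_peaks.
#' @param tolerance Relative migration tolerance.
#' @return Integer study fragment id per centroid row.
#' @keywords internal
merge_organ_centroids <- function(cent, tolerance = 0.02) {
  ord <- order(cent$migration_time_s)
  n <- nrow(cent)
  cl <- integer(n)
  groups <- list()  # member row indices per study fragment
  for (i in ord) {
    t_i <- cent$migration_time_s[i]
    se_i <- cent$sd_migration[i] / sqrt(max(cent$n_peaks[i], 1))
    placed <- FALSE
    if (length(groups)) {
      means <- vapply(groups, function(g) mean(cent$migration_time_s[g]), numeric(1))
      dev <- abs(t_i - means) / means
      for (j in order(dev)) {
        if (dev[j] >= tolerance) break
        g <- groups[[j]]
        if (cent$organ[i] %in% cent$organ[g]) next
        se_j <- sqrt(mean((cent$sd_migration[g]^2) / pmax(cent$n_peaks[g], 1)))
        gap <- abs(t_i - means[j])
        close_enough <- if (se_i == 0 && se_j == 0) gap == 0 else
          gap <= 3 * sqrt(se_i^2 + se_j^2)
        if (!close_enough) next
        groups[[j]] <- c(g, i)
        placed <- TRUE
        cl[i] <- j
        break
      }
    }
    if (!placed) {
      groups[[length(groups) + 1L]] <- i
      cl[i] <- length(groups)
    }
  }
  means <- vapply(groups, function(g) mean(cent$migration_time_s[g]), numeric(1))
  rk <- rank(means, ties.method = "first")
  rk[cl]
}

#' Filter fragments by biological-replicate support
#'
#' A fragment is a meaningful PMI indicator for an organ only if, at one
#' or more PMI time points, it is detected in at least `min_support` of
#' the biological replicates (default 5 of 6). Fragments failing the rule
#' in an organ lose that organ from their membership set; their peaks in
#' that organ become unassigned (fragment_id NA). Fragments losing all
#' organs are removed.
#'
#' @param study_catalog A [build_study_catalog()] result.
#' @param manifest Training-cohort manifest (replicate groups are organ
#'   by PMI day).
#' @param min_support Minimum replicates a fragment must appear in.
#' @param replicates Nominal replicate-group size; groups smaller than
#'   `min_support` are skipped with a warning.
#' @return The filtered `study_catalog` (same structure; fragment ids kept).
#' @export
filter_by_replicate_support <- function(study_catalog, manifest,
                                        min_support = 5L, replicates = 6L) {
  pk <- study_catalog$peaks
  man <- manifest[manifest$cohort == "training", ]
  pk <- merge(pk, man[, c("sample_id", "rat_id", "pmi_day")], by = "sample_id")
  keep_pairs <- list()
  for (organ in unique(pk$organ)) {
    po <- pk[pk$organ == organ, ]
    for (day in unique(po$pmi_day)) {
      grp <- po[po$pmi_day == day, ]
      n_rep <- length(unique(man$rat_id[man$organ == organ & man$pmi_day == day]))
      if (n_rep < min_support) {
        warning(sprintf("replicate group %s/day %s has only %d replicates; skipped",
                        organ, format(day), n_rep))
        next
      }
      supp <- tapply(grp$rat_id, grp$fragment_id, function(r) length(unique(r)))
      ok <- as.integer(names(supp))[supp >= min_support]
      if (length(ok)) keep_pairs[[paste(organ, day)]] <-
          data.frame(organ = organ, fragment_id = ok)
    }
  }
  keep <- unique(do.call(rbind, keep_pairs))
  frags <- study_catalog$fragments
  new_organs <- lapply(seq_len(nrow(frags)), function(i) {
    fid <- frags$fragment_id[i]
    intersect(frags$organs[[i]], keep$organ[keep$fragment_id == fid])
  })
  frags$organs <- new_organs
  retained <- lengths(new_organs) > 0
  frags <- frags[retained, , drop = FALSE]

  out_peaks <- study_catalog$peaks
  valid <- paste(out_peaks$organ, out_peaks$fragment_id) %in%
    paste(keep$organ, keep$fragment_id)
  out_peaks$fragment_id[!valid] <- NA_integer_
  out <- study_catalog
  out$fragments <- frags
  out$peaks <- out_peaks
  out
}

#' Assign new peaks to an existing catalog
#'
#' Used at predict time for the external cohort: each peak is assigned to
#' the nearest catalog fragment by relative migration deviation when that
#' deviation is below the tolerance; unmatched peaks are dropped with a
#' message (no new fragments are created at predict time).
#'
#' @param peaks External peak table.
#' @param study_catalog Filtered training catalog.
#' @param tolerance Relative migration tolerance.
#' @param manifest Manifest supplying organ per sample.
#' @return Peaks with a study-wide `fragment_id` column (unmatched rows dropped).
#' @export
assign_to_catalog <- function(peaks, study_catalog, manifest, tolerance = 0.02) {
  frag <- study_catalog$fragments
  man <- manifest[, c("sample_id", "organ")]
  pk <- merge(peaks, man, by = "sample_id")
  dev <- abs(outer(pk$migration_time_s, frag$mean_migration, "-")) /
    matrix(frag$mean_migration, nrow(pk), nrow(frag), byrow = TRUE)
  j <- max.col(-dev, ties.method = "first")
  best <- dev[cbind(seq_len(nrow(pk)), j)]
  pk$fragment_id <- frag$fragment_id[j]
  # respect organ membership: a peak may only map to a fragment present in its organ
  in_organ <- mapply(function(fi, o) o %in% frag$organs[[match(fi, frag$fragment_id)]],
                     pk$fragment_id, pk$organ)
  ok <- best < tolerance & in_organ
  if (any(!ok)) {
    message(sum(!ok), " external peak(s) did not match the training catalog; dropped")
  }
  pk[ok, , drop = FALSE]
}

#' Build the per-organ feature matrix
#'
#' One row per sample of the organ, one column per fragment retained for
#' that organ; a cell holds the assigned peak height, 0 where the
#' fragment was not detected. When two peaks of one sample map to the
#' same fragment the taller is kept (logged via `message`).
#'
#' @param study_catalog Filtered catalog (training) whose `peaks` carry
#'   study-wide assignments, or any peak data.frame with `sample_id`,
#'   `organ`, `fragment_id`, `peak_height` via `peaks =`.
#' @param manifest Manifest rows for the samples wanted (any cohort).
#' @param organ Organ to build the matrix for.
#' @param peaks Optional explicit assigned-peak table overriding
#'   `study_catalog$peaks` (used for the external cohort).
#' @return list of class `feature_matrix`: `x` (numeric matrix, rownames
#'   sample_id, colnames fragment ids as `F<k>`), `label` (factor of PMI
#'   days), `meta` (manifest rows, aligned).
#' @export
build_feature_matrix <- function(study_catalog, manifest, organ, peaks = NULL) {
  stopifnot(organ %in% pmi_organs())
  frag <- study_catalog$fragments
  has_organ <- vapply(frag$organs, function(s) organ %in% s, logical(1))
  fids <- frag$fragment_id[has_organ]
  pk <- if (is.null(peaks)) study_catalog$peaks else peaks
  seen <- unique(pk$sample_id[pk$organ == organ])
  pk <- pk[!is.na(pk$fragment_id) & pk$organ == organ, , drop = FALSE]
  man <- manifest[manifest$organ == organ, , drop = FALSE]
  if (!nrow(man)) stop("no samples of organ ", organ, " in manifest")
  absent <- setdiff(man$sample_id, seen)
  if (length(absent)) {
    stop("manifest sample(s) with no peak table: ", paste(absent, collapse = ", "))
  }
  x <- matrix(0, nrow(man), length(fids),
              dimnames = list(man$sample_id, paste0("F", fids)))
  pk <- pk[pk$sample_id %in% man$sample_id, , drop = FALSE]
  if (nrow(pk)) {
    dup <- duplicated(pk[, c("sample_id", "fragment_id")])
    if (any(dup)) {
      message(sum(dup), " duplicate peak assignment(s) in ", organ,
              "; keeping the taller peak per (sample, fragment)")
    }
    agg <- stats::aggregate(peak_height ~ sample_id + fragment_id, data = pk, FUN = max)
    agg <- agg[agg$fragment_id %in% fids, , drop = FALSE]
    x[cbind(match(agg$sample_id, man$sample_id),
            match(paste0("F", agg$fragment_id), colnames(x)))] <- agg$peak_height
  }
  structure(list(x = x,
                 label = factor(man$pmi_day, levels = sort(unique(manifest$pmi_day))),
                 meta = man),
            class = "feature_matrix")
}

#' Standardize feature matrices on training statistics
#'
#' Per-column z-scores with mean and SD estimated on the training matrix
#' only; the identical transform is applied to every other matrix
#' (internal test, external cohort). Zero-variance columns are centered
#' and left unscaled.
#'
#' @param train A `feature_matrix` (or plain matrix).
#' @param others List of further `feature_matrix`/matrix objects sharing
#'   the training columns.
#' @return list(train, others, center, scale); inputs keep their class,
#'   with `x` replaced by the standardized values.
#' @export
standardize_features <- function(train, others = list()) {
  get_x <- function(m) if (inherits(m, "feature_matrix")) m$x else m
  set_x <- function(m, x) { if (inherits(m, "feature_matrix")) { m$x <- x; m } else x }
  xt <- get_x(train)
  stopifnot(nrow(xt) > 0)
  ctr <- colMeans(xt)
  scl <- apply(xt, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1  # zero-variance columns pass through centered
  tx <- function(x) sweep(sweep(x, 2, ctr), 2, scl, "/")
  list(train = set_x(train, tx(xt)),
       others = lapply(others, function(m) set_x(m, tx(get_x(m)))),
       center = ctr, scale = scl)
}
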