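#' Organ labels used throughout the study
#'
#' The four rat organs profiled by the lab-on-chip study, in the fixed
#' order used by every table and figure export.
#'
#' @return Character vector `c("lung", "liver", "kidney", "muscle")`.
#' @export
pmi_organs <- function() c("lung", "liver", "kidney", "muscle")

#' Load the reference polypeptide-fragment catalog
#'
#' Reads the packaged catalog of the 45 polypeptide fragments resolved by
#' microfluidic capillary electrophoresis across the four organs: each
#' fragment has a mean molecular mass (kDa, within the 14--230 kDa
#' separation range of the Protein 230 kit), a mean migration time
#' (seconds) with its standard deviation, and the set of organs in which
#' it was observed. Fragments are numbered by ascending migration time.
#'
#' @param path Path to a catalog CSV. Defaults to the packaged fixture.
#' @return A data.frame with columns `fragment_id`, `mean_mass`, `sd_mass`,
#'   `mean_migration`, `sd_migration` and a list-column `organs`.
#' @examples
#' cat45 <- load_reference_catalog()
#' nrow(cat45)  # 45
#' @export
load_reference_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "fragment_catalog.csv", package = "pmifusion")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("reference fragment catalog not found: ", path)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("fragment_id", "mean_mass", "sd_mass",
              "mean_migration", "sd_migration", "organs")
  if (!all(needed %in% names(raw))) {
    stop("corrupt catalog file: missing columns ",
         paste(setdiff(needed, names(raw)), collapse = ", "))
  }
  raw$organs <- strsplit(raw$organs, ";", fixed = TRUE)
  validate_catalog(raw)
  raw
}

#' @keywords internal
validate_catalog <- function(catalog) {
  if (anyDuplicated(catalog$fragment_id)) stop("fragment_ids must be unique")
  if (any(lengths(catalog$organs) == 0)) stop("every fragment needs >=1 organ")
  bad <- unlist(catalog$organs)[!unlist(catalog$organs) %in% pmi_organs()]
  if (length(bad)) stop("unknown organ label(s): ", paste(unique(bad), collapse = ", "))
  ord <- order(catalog$fragment_id)
  if (is.unsorted(catalog$mean_migration[ord], strictly = TRUE)) {
    stop("mean migration times must be strictly increasing in fragment_id order")
  }
  if (any(catalog$mean_mass < 14 | catalog$mean_mass > 230)) {
    stop("mean masses must lie in the 14-230 kDa separation range")
  }
  invisible(catalog)
}

#' Summarise organ membership of a fragment catalog
#'
#' Computes, from a catalog's organ sets, the per-organ fragment totals,
#' how many fragments are shared by exactly k organs (k = 1..4), and how
#' many are exclusive to each organ.
#'
#' @param catalog A catalog data.frame with a list-column `organs`
#'   (as returned by [load_reference_catalog()] or [match_fragments()]).
#' @return A list with `total` (fragment count), `per_organ` (named
#'   integer vector), `shared_by` (named vector, `"1"`..`"4"`), and
#'   `exclusive` (named integer vector).
#' @export
organ_membership_summary <- function(catalog) {
  stopifnot(is.list(catalog$organs))
  norg <- lengths(catalog$organs)
  per_organ <- vapply(pmi_organs(), function(o) {
    sum(vapply(catalog$organs, function(s) o %in% s, logical(1)))
  }, integer(1))
  shared_by <- vapply(1:4, function(k) sum(norg == k), integer(1))
  names(shared_by) <- as.character(1:4)
  exclusive <- vapply(pmi_organs(), function(o) {
    sum(vapply(catalog$organs, function(s) identical(s, o), logical(1)))
  }, integer(1))
  list(total = nrow(catalog), per_organ = per_organ,
       shared_by = shared_by, exclusive = exclusive)
}
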