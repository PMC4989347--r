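#' Inclusion-filter configuration
#'
#' Bundles the coverage, quality and known-variant exclusion filters applied
#' to every SNS signature before partitioning. The defaults mirror a typical
#' exome workflow: a minimum of 8x coverage and removal of variants present
#' in a dbSNP-style catalogue supplied as an exclusion set. No numeric
#' quality cut-off is imposed by default (`min_qual = 0`), since "standard"
#' quality thresholds vary by caller.
#'
#' @param min_depth Minimum read depth for inclusion (default 8). Variants
#'   lacking a depth annotation pass this filter but are tallied separately.
#' @param min_qual Minimum variant quality (default 0 = off).
#' @param exclusion_sets Named list of character vectors of variant keys
#'   (as from [read_exclusion_list()]), e.g.
#'   `list(dbSNP129 = keys)`. Names must be unique.
#' @return A `filter_config` object.
#' @export
filter_config <- function(min_depth = 8, min_qual = 0,
                          exclusion_sets = list()) {
  stopifnot(min_depth >= 0, min_qual >= 0, is.list(exclusion_sets))
  if (length(exclusion_sets) > 0) {
    if (is.null(names(exclusion_sets)) ||
        anyDuplicated(names(exclusion_sets)) ||
        any(!nzchar(names(exclusion_sets)))) {
      abort("exclusion_sets must be a uniquely named list")
    }
  }
  structure(
    list(min_depth = as.integer(min_depth), min_qual = as.numeric(min_qual),
         exclusion_sets = exclusion_sets),
    class = "filter_config"
  )
}

#' Apply inclusion filters to a variant set
#'
#' Filters are evaluated as independent per-variant predicates, so the
#' retained set does not depend on application order; removals are
#' *attributed* in the fixed order depth, then quality, then each exclusion
#' set in the order given (a variant failing several criteria is counted
#' against the first).
#'
#' @param vs A [variant_set()].
#' @param cfg A [filter_config()].
#' @return A list with `variants` (the filtered [variant_set()]) and
#'   `report`, a tibble of `criterion` / `n_removed` rows plus the counts of
#'   variants lacking depth or quality annotations
#'   (`missing_depth`, `missing_qual`: retained, not removed).
#' @export
#' @examples
#' vs <- variant_set(variant_tbl("1", 1:3, "C", "T", depth = c(5, 50, NA)),
#'                   "s", "PTC")
#' apply_filters(vs, filter_config(min_depth = 8))$report
apply_filters <- function(vs, cfg = filter_config()) {
  stopifnot(inherits(vs, "variant_set"), inherits(cfg, "filter_config"))
  v <- vs$variants
  keys <- variant_keys(vs)
  pass_depth <- is.na(v$depth) | v$depth >= cfg$min_depth
  pass_qual <- is.na(v$qual) | v$qual >= cfg$min_qual
  excl_fail <- lapply(cfg$exclusion_sets, function(ks) keys %in% ks)
  report <- tibble(
    criterion = c("depth", "qual",
                  if (length(excl_fail)) paste0("exclusion:",
                                                names(cfg$exclusion_sets))),
    n_removed = 0L
  )
  removed <- !pass_depth
  report$n_removed[report$criterion == "depth"] <- sum(removed)
  fail_q <- !pass_qual & !removed
  report$n_removed[report$criterion == "qual"] <- sum(fail_q)
  removed <- removed | !pass_qual
  for (nm in names(excl_fail)) {
    fail_e <- excl_fail[[nm]] & !removed
    report$n_removed[report$criterion == paste0("exclusion:", nm)] <-
      sum(fail_e)
    removed <- removed | excl_fail[[nm]]
  }
  out <- variant_set(v[!removed, , drop = FALSE], vs$sample_id, vs$tissue)
  report <- dplyr::bind_rows(
    report,
    tibble(criterion = c("missing_depth", "missing_qual"),
           n_removed = c(sum(is.na(v$depth)), sum(is.na(v$qual))))
  )
  list(variants = out, report = report)
}

#' Filter a whole cohort
#'
#' Applies the same [filter_config()] to every sample (PTC, ANT and blood) of
#' an [load_cohort()] object, so all downstream intersections operate on a
#' comparable key space.
#'
#' @param cohort An `sns_cohort`.
#' @param cfg A [filter_config()].
#' @return A filtered `sns_cohort`; per-sample filter reports are attached as
#'   attribute `filter_reports`.
#' @export
filter_cohort <- function(cohort, cfg = filter_config()) {
  stopifnot(inherits(cohort, "sns_cohort"))
  reports <- list()
  patients <- list()
  for (pid in names(cohort$patients)) {
    p <- cohort$patients[[pid]]
    filt <- list()
    for (nm in c("ptc", "ant", "blood")) {
      if (is.null(p[[nm]])) {
        filt[nm] <- list(NULL)
      } else {
        r <- apply_filters(p[[nm]], cfg)
        filt[[nm]] <- r$variants
        reports[[r$variants$sample_id]] <- r$report
      }
    }
    patients[[pid]] <- filt
  }
  out <- structure(list(manifest = cohort$manifest, patients = patients),
                   class = "sns_cohort")
  attr(out, "filter_reports") <- reports
  out
}

#' Filter-robustness sweep
#'
#' Re-runs the full partition + spectrum pipeline under each of several
#' filter configurations and tabulates the per-subset substitution spectra,
#' so that the direction of any spectral shift can be checked for robustness
#' to the level of SNS filtering.
#'
#' @param cohort An `sns_cohort`.
#' @param configs Named list of [filter_config()]s (>= 1).
#' @return A tibble with columns `config`, `patient_id`, `subset`, `class`,
#'   `count` and `proportion` (per patient-subset proportions).
#' @export
filter_sweep <- function(cohort, configs) {
  stopifnot(length(configs) >= 1)
  if (is.null(names(configs)) || any(!nzchar(names(configs)))) {
    names(configs) <- paste0("config", seq_along(configs))
  }
  dplyr::bind_rows(lapply(names(configs), function(nm) {
    parts <- partition_cohort(cohort, configs[[nm]])
    tab <- cohort_spectrum_table(parts)
    tab$config <- nm
    tab[, c("config", setdiff(names(tab), "config"))]
  }))
}
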