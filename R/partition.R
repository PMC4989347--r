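#' Partition a patient's tumor/normal SNS signatures at their branch point
#'
#' The central operation: intersecting the tumor (PTC) signature with its
#' matched adjacent-non-tumor (ANT) signature splits each patient's SNSs
#' into three disjoint subsets that order them on a rudimentary phylogeny of
#' the gland —
#'
#' * **common** — present in both tissues: the patient's germline plus
#'   everything accrued before divergence of the malignant and
#'   non-malignant thyrocyte lineages;
#' * **unique_ptc** / **unique_ant** — present in one tissue only: late
#'   somatic events accrued after that divergence.
#'
#' If a blood signature is supplied, each subset is additionally intersected
#' with it: blood diverges from the thyrocyte lineage early in
#' embryogenesis, so a high blood overlap marks a subset as evolutionarily
#' old.
#'
#' @param ptc,ant [variant_set()]s of the matched tumor and adjacent
#'   non-tumor samples. Matching is by bare variant key (chrom, pos, ref,
#'   alt); genotypes play no role.
#' @param blood Optional blood [variant_set()] from the same patient.
#' @param patient_id Patient identifier stamped on the partition.
#' @return An object of class `trio_partition`: `patient_id`, the three
#'   subset [variant_set()]s, `shared_fraction_ptc` =
#'   `|common| / |PTC|` (`NA` for an empty PTC set), and — when blood is
#'   given — `blood_overlap`, a named numeric of per-subset fractions
#'   `|subset %in% blood| / |subset|` (`NA` for an empty subset), and
#'   `blood` itself.
#' @export
#' @examples
#' p <- variant_set(variant_tbl("1", 1:5, "C", "T"), "p1_PTC", "PTC")
#' a <- variant_set(variant_tbl("1", 3:8, "C", "T"), "p1_ANT", "ANT")
#' partition_trio(p, a, patient_id = "p1")$shared_fraction_ptc  # 3/5
partition_trio <- function(ptc, ant, blood = NULL, patient_id = NULL) {
  stopifnot(inherits(ptc, "variant_set"), inherits(ant, "variant_set"))
  if (is.null(patient_id)) {
    pid_p <- sub("_(PTC|ANT|BLOOD)$", "", ptc$sample_id)
    pid_a <- sub("_(PTC|ANT|BLOOD)$", "", ant$sample_id)
    if (!identical(pid_p, pid_a)) {
      abort(paste0("PTC sample '", ptc$sample_id, "' and ANT sample '",
                   ant$sample_id, "' appear to come from different patients;",
                   " pass patient_id explicitly to override"))
    }
    patient_id <- pid_p
  }
  kp <- variant_keys(ptc)
  ka <- variant_keys(ant)
  common_keys <- intersect(kp, ka)
  out <- list(
    patient_id = patient_id,
    common = variant_set_subset(ptc, common_keys),
    unique_ptc = variant_set_subset(ptc, setdiff(kp, ka)),
    unique_ant = variant_set_subset(ant, setdiff(ka, kp)),
    shared_fraction_ptc = if (length(kp) > 0) {
      length(common_keys) / length(kp)
    } else {
      NA_real_
    }
  )
  out$common$sample_id <- paste0(patient_id, "_common")
  out$unique_ptc$sample_id <- paste0(patient_id, "_unique_ptc")
  out$unique_ant$sample_id <- paste0(patient_id, "_unique_ant")
  if (!is.null(blood)) {
    stopifnot(inherits(blood, "variant_set"))
    kb <- variant_keys(blood)
    frac <- function(keys) {
      if (length(keys) == 0) NA_real_ else mean(keys %in% kb)
    }
    out$blood_overlap <- c(
      common = frac(common_keys),
      unique_ptc = frac(setdiff(kp, ka)),
      unique_ant = frac(setdiff(ka, kp))
    )
    out$blood <- blood
  }
  structure(out, class = "trio_partition")
}

#' @export
print.trio_partition <- function(x, ...) {
  cat(sprintf(
    "<trio_partition> %s: common %d | unique_ptc %d | unique_ant %d (shared %.1f%%)\n",
    x$patient_id, length(x$common), length(x$unique_ptc),
    length(x$unique_ant), 100 * x$shared_fraction_ptc))
  if (!is.null(x$blood_overlap)) {
    cat(sprintf("  blood overlap: common %.2f, unique_ptc %.2f, unique_ant %.2f\n",
                x$blood_overlap[["common"]], x$blood_overlap[["unique_ptc"]],
                x$blood_overlap[["unique_ant"]]))
  }
  invisible(x)
}

#' Partition every patient of a cohort
#'
#' Applies the inclusion filters to each sample and then [partition_trio()]
#' per patient. Blood sets pass through the same [filter_config()] as the
#' tissue sets so all fractions live in one key space.
#'
#' @param cohort An `sns_cohort` from [load_cohort()].
#' @param cfg A [filter_config()]; use `filter_config(min_depth = 0)` for no
#'   filtering.
#' @return Named list of `trio_partition`s, one per patient, carrying the
#'   manifest as attribute `manifest`.
#' @export
partition_cohort <- function(cohort, cfg = filter_config()) {
  stopifnot(inherits(cohort, "sns_cohort"))
  filtered <- filter_cohort(cohort, cfg)
  parts <- lapply(names(filtered$patients), function(pid) {
    p <- filtered$patients[[pid]]
    partition_trio(p$ptc, p$ant, blood = p$blood, patient_id = pid)
  })
  names(parts) <- names(filtered$patients)
  attr(parts, "manifest") <- cohort$manifest
  parts
}

subset_keys <- function(part, subset) {
  if (subset == "blood") {
    if (is.null(part$blood)) return(NULL)
    return(variant_keys(part$blood))
  }
  variant_keys(part[[subset]])
}

#' Inter-patient overlap of a named subset
#'
#' Quantifies cohort heterogeneity: for patients `i != j`,
#' `overlap(i, j) = |S_i intersect S_j| / |S_i|` where `S` is the named
#' subset (or the blood signature). The matrix is asymmetric by design —
#' row `i` asks what fraction of patient `i`'s SNSs recur in patient `j`.
#'
#' @param partitions List of `trio_partition`s (>= 2 patients).
#' @param subset One of `"common"`, `"unique_ptc"`, `"unique_ant"`,
#'   `"blood"`.
#' @param metric `"directional"` (default, the asymmetric fraction above) or
#'   `"jaccard"` (`|S_i intersect S_j| / |S_i union S_j|`, symmetric).
#' @return A list with `matrix` (patients x patients, `NA` diagonal; rows of
#'   patients with an empty subset are all `NA`), `patient_means` (mean over
#'   `j != i`, `NA` for undefined rows) and `cohort_mean` (mean of defined
#'   patient means).
#' @export
pairwise_overlap <- function(partitions,
                             subset = c("common", "unique_ptc", "unique_ant",
                                        "blood"),
                             metric = c("directional", "jaccard")) {
  subset <- match.arg(subset)
  metric <- match.arg(metric)
  keysets <- lapply(partitions, subset_keys, subset = subset)
  names(keysets) <- vapply(partitions, `[[`, "", "patient_id")
  keysets <- keysets[!vapply(keysets, is.null, logical(1))]
  if (length(keysets) < 2) {
    abort("pairwise_overlap needs at least 2 patients with the subset present")
  }
  ids <- names(keysets)
  n <- length(keysets)
  m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  sizes <- lengths(keysets)
  for (i in seq_len(n)) {
    if (sizes[[i]] == 0) next  # undefined row, flagged NA
    for (j in seq_len(n)) {
      if (i == j) next
      inter <- length(intersect(keysets[[i]], keysets[[j]]))
      m[i, j] <- if (metric == "directional") {
        inter / sizes[[i]]
      } else {
        inter / (sizes[[i]] + sizes[[j]] - inter)
      }
    }
  }
  patient_means <- rowMeans(m, na.rm = TRUE)
  patient_means[sizes == 0] <- NA_real_
  list(matrix = m, patient_means = patient_means,
       cohort_mean = mean(patient_means, na.rm = TRUE))
}

#' Blood concordance of the three subsets across a cohort
#'
#' Summarises, over all patients with a blood sample, what fraction of each
#' subset's SNSs recur in the matched blood, and contrasts the common
#' subset's fractions against the pooled unique-subset fractions with a
#' two-sided Welch two-sample t-test. Under the early-divergence model the
#' common subset should overlap blood heavily and the unique subsets hardly
#' at all.
#'
#' @param partitions List of `trio_partition`s.
#' @return A list with `per_patient` (tibble patient x subset fractions),
#'   `means` (named numeric over subsets, empty subsets excluded), `test`
#'   (an `htest` from [stats::t.test()]; `NULL` with a warning when fewer
#'   than 2 blood samples are available, or when the fractions are constant
#'   on both sides so no t statistic exists) and `p_value` (from the test;
#'   for the constant-fractions degenerate case 1 if the group means agree
#'   and 0 otherwise).
#' @export
blood_concordance_summary <- function(partitions) {
  rows <- lapply(partitions, function(p) {
    if (is.null(p$blood_overlap)) return(NULL)
    tibble(patient_id = p$patient_id,
           subset = names(p$blood_overlap),
           fraction = unname(p$blood_overlap))
  })
  per_patient <- dplyr::bind_rows(rows)
  if (nrow(per_patient) == 0) {
    abort("no patients carry blood overlap information")
  }
  means <- named_vec(tapply(per_patient$fraction, per_patient$subset,
                            mean,
                            na.rm = TRUE)[c("common", "unique_ptc",
                                            "unique_ant")])
  n_blood <- length(unique(per_patient$patient_id))
  test <- NULL
  p_value <- NA_real_
  if (n_blood >= 2) {
    common_f <- per_patient$fraction[per_patient$subset == "common"]
    unique_f <- per_patient$fraction[per_patient$subset != "common"]
    common_f <- common_f[!is.na(common_f)]
    unique_f <- unique_f[!is.na(unique_f)]
    if (stats::var(common_f) + stats::var(unique_f) > 0) {
      test <- stats::t.test(common_f, unique_f, var.equal = FALSE)
      p_value <- test$p.value
    } else {
      p_value <- as.numeric(isTRUE(all.equal(mean(common_f), mean(unique_f))))
    }
  } else {
    warn("fewer than 2 blood samples: reporting means without a test")
  }
  list(per_patient = per_patient, means = means, test = test,
       p_value = p_value)
}
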