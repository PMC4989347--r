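#' Predicted-deleterious burden per subset
#'
#' Attaches upstream predictor votes to each patient's partitioned subsets
#' and summarises, per patient and subset, the number of SNSs, the number of
#' non-synonymous coding SNSs, and the number of those called damaging by at
#' least `vote_threshold` of the five predictors, together with the
#' per-coding-variant deleterious rate. Each unique subset is contrasted
#' against the Common subset (and, if given, an external comparison cohort)
#' by two-sided Welch t-tests on the per-patient rates.
#'
#' Variants without an entry in `votes` count as 0 votes; their number is
#' reported as `n_missing_votes` so sparse annotation coverage is visible.
#'
#' @param partitions List of `trio_partition`s with `consequence`
#'   annotations.
#' @param votes Named integer vector (0-5) keyed by variant key, as from
#'   [read_deleteriousness_table()].
#' @param vote_threshold Minimum votes (1-5, default 1) to call a variant
#'   predicted-deleterious. The count is non-increasing in the threshold.
#' @param comparison Optional list of [variant_set()]s (e.g. external blood
#'   genomes) given the same treatment, one rate per set.
#' @return A list: `records` (tibble of per patient x subset burden rows
#'   with columns `patient_id`, `subset`, `n_sns`, `n_coding`,
#'   `n_nonsynonymous`, `n_predicted_deleterious`, `rate`,
#'   `n_missing_votes`), `means` (per-subset mean rates), `tests` (Welch
#'   contrasts unique-vs-common and, when supplied, subset-vs-comparison),
#'   and `comparison_records` (or `NULL`).
#' @export
deleterious_burden <- function(partitions, votes, vote_threshold = 1,
                               comparison = NULL) {
  stopifnot(vote_threshold >= 1, vote_threshold <= 5)
  summarise_one <- function(v, patient_id, subset) {
    keys <- if (nrow(v) > 0) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
      else character()
    vt <- unname(votes[keys])
    n_missing <- sum(is.na(vt))
    vt[is.na(vt)] <- 0L
    coding <- v$consequence %in% CODING_CLASSES
    nonsyn <- v$consequence %in% NONSYN_CLASSES
    n_del <- sum(nonsyn & vt >= vote_threshold)
    tibble(
      patient_id = patient_id, subset = subset,
      n_sns = nrow(v), n_coding = sum(coding),
      n_nonsynonymous = sum(nonsyn),
      n_predicted_deleterious = n_del,
      rate = if (any(coding)) n_del / sum(coding) else NA_real_,
      n_missing_votes = n_missing
    )
  }
  rows <- list()
  for (p in partitions) {
    for (s in c("common", "unique_ptc", "unique_ant")) {
      rows[[length(rows) + 1]] <- summarise_one(p[[s]]$variants,
                                                p$patient_id, s)
    }
  }
  records <- dplyr::bind_rows(rows)
  if (any(records$n_missing_votes > 0)) {
    warn(paste0(sum(records$n_missing_votes),
                " variant(s) lack deleteriousness votes; treated as 0 votes"))
  }
  ok <- !is.na(records$rate)
  means <- named_vec(tapply(records$rate[ok], records$subset[ok],
                            mean)[c("common", "unique_ptc", "unique_ant")])
  rate_of <- function(s) records$rate[records$subset == s & ok]
  tests <- list(
    unique_ptc_vs_common = safe_welch(rate_of("unique_ptc"),
                                      rate_of("common")),
    unique_ant_vs_common = safe_welch(rate_of("unique_ant"),
                                      rate_of("common"))
  )
  comparison_records <- NULL
  if (!is.null(comparison)) {
    comparison_records <- dplyr::bind_rows(lapply(comparison, function(vs) {
      summarise_one(vs$variants, vs$sample_id, "comparison")
    }))
    if (any(comparison_records$n_missing_votes > 0)) {
      warn(paste0(sum(comparison_records$n_missing_votes),
                  " comparison variant(s) lack deleteriousness votes;",
                  " treated as 0 votes"))
    }
    cmp_rates <- comparison_records$rate[!is.na(comparison_records$rate)]
    tests$unique_ptc_vs_comparison <- safe_welch(rate_of("unique_ptc"),
                                                 cmp_rates)
    tests$unique_ant_vs_comparison <- safe_welch(rate_of("unique_ant"),
                                                 cmp_rates)
  }
  list(records = records, means = means, tests = tests,
       comparison_records = comparison_records)
}

#' Per-patient total SNS counts
#'
#' Counts the SNSs of each patient's filtered PTC (or ANT) signature —
#' equivalently `|common| + |unique_*|` — the quantity the cohort burden
#' associations operate on.
#'
#' @param partitions List of `trio_partition`s.
#' @param tissue `"PTC"` (default) or `"ANT"`.
#' @return Tibble `patient_id`, `n_sns`.
#' @export
cohort_sns_totals <- function(partitions, tissue = c("PTC", "ANT")) {
  tissue <- match.arg(tissue)
  uniq <- if (tissue == "PTC") "unique_ptc" else "unique_ant"
  dplyr::bind_rows(lapply(partitions, function(p) {
    tibble(patient_id = p$patient_id,
           n_sns = length(p$common) + length(p[[uniq]]))
  }))
}

#' Association of SNS burden with clinical grouping variables
#'
#' Compares per-patient total SNS counts between clinical groups: BRAF
#' mutation status, age dichotomised at 45 years, sex, TNM stage, or
#' histology. Two groups are contrasted by a two-sided Welch two-sample
#' t-test; three or more by one-way ANOVA.
#'
#' @param totals Tibble `patient_id`, `n_sns` (see [cohort_sns_totals()]).
#' @param manifest Cohort manifest tibble (see [read_manifest()]).
#' @param grouping One of `"braf"`, `"age45"`, `"sex"`, `"stage"`,
#'   `"histology"`.
#' @param age_cut Age boundary for `"age45"` (default 45). Patients aged
#'   exactly `age_cut` fall in the younger group ("older than 45" vs
#'   "under 45"); set `older_inclusive = TRUE` to move the boundary age to
#'   the older group.
#' @param older_inclusive See `age_cut`.
#' @return A list: `by_group` (tibble `group`, `n`, `mean`, `sd`), `test`
#'   (Welch `htest`, ANOVA `aov` summary, or `NULL` with a warning when any
#'   group has fewer than 2 patients), `p_value`.
#' @export
burden_by_group <- function(totals, manifest,
                            grouping = c("braf", "age45", "sex", "stage",
                                         "histology"),
                            age_cut = 45, older_inclusive = FALSE) {
  grouping <- match.arg(grouping)
  df <- dplyr::inner_join(totals, manifest, by = "patient_id")
  group <- switch(
    grouping,
    braf = ifelse(df$braf_mutant, "BRAF-mutant", "BRAF-wildtype"),
    age45 = if (older_inclusive) {
      ifelse(df$age >= age_cut, paste0(">=", age_cut), paste0("<", age_cut))
    } else {
      ifelse(df$age > age_cut, paste0(">", age_cut), paste0("<=", age_cut))
    },
    sex = df$sex,
    stage = df$tnm_stage,
    histology = df$histology
  )
  keep <- !is.na(group) & !is.na(df$n_sns)
  df <- df[keep, ]
  group <- group[keep]
  by_group <- dplyr::arrange(dplyr::summarise(
    dplyr::group_by(tibble(group = group, n_sns = df$n_sns), .data$group),
    n = dplyr::n(), mean = mean(.data$n_sns), sd = stats::sd(.data$n_sns),
    .groups = "drop"), .data$group)
  test <- NULL
  p <- NA_real_
  if (dplyr::n_distinct(group) < 2 || any(by_group$n < 2)) {
    warn("degenerate group sizes: reporting means without a test")
  } else if (dplyr::n_distinct(group) == 2) {
    test <- stats::t.test(df$n_sns ~ group, var.equal = FALSE)
    p <- test$p.value
  } else {
    test <- stats::oneway.test(df$n_sns ~ group, var.equal = TRUE)
    p <- test$p.value
  }
  list(by_group = by_group, test = test, p_value = p)
}
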