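SUBSTITUTION_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
TRANSITION_CLASSES <- c("C>T", "T>C")

complement_base <- function(x) chartr("ACGT", "TGCA", x)

#' Strand-collapsed substitution class of an SNS
#'
#' Maps each of the 12 directed `ref>alt` substitutions onto the six
#' pyrimidine-reference classes `C>A, C>G, C>T, T>A, T>C, T>G` by
#' reverse-complementing substitutions whose reference base is a purine.
#' Collapsing is required for exome-wide "C-to-X" classes to be
#' well-defined regardless of which strand a call was reported on.
#'
#' @param ref,alt Character vectors of single bases (`A,C,G,T`,
#'   `ref != alt`), recycled to a common length.
#' @param collapse If `FALSE`, return the directed 12-class label instead
#'   (diagnostic use).
#' @return Character vector of class labels.
#' @export
#' @examples
#' classify_substitution("G", "A")  # "C>T": a transition, strand-collapsed
classify_substitution <- function(ref, alt, collapse = TRUE) {
  if (any(!ref %in% DNA_BASES) || any(!alt %in% DNA_BASES)) {
    abort("ref and alt must be single bases in A,C,G,T")
  }
  if (any(ref == alt)) abort("ref and alt must differ")
  if (collapse) {
    flip <- ref %in% c("A", "G")
    ref[flip] <- complement_base(ref[flip])
    alt[flip] <- complement_base(alt[flip])
  }
  paste0(ref, ">", alt)
}

#' Is a substitution class a transition?
#'
#' @param class_label Strand-collapsed class labels.
#' @return Logical: `TRUE` for `C>T` and `T>C`, `FALSE` for the four
#'   transversion classes.
#' @export
is_transition <- function(class_label) class_label %in% TRANSITION_CLASSES

#' Mutational spectrum of a variant collection
#'
#' Tallies a collection of SNSs into the six strand-collapsed substitution
#' classes and computes the transition:transversion (Tr:Tv) ratio.
#'
#' @param x A [variant_set()] or a variant table with `ref`/`alt` columns.
#' @return An object of class `spectrum_summary`: `counts` (named integer
#'   over the six classes), `total`, `proportions` (all `NA` when
#'   `total == 0`), and `tr_tv_ratio` (`NA` when the collection has no
#'   transversions).
#' @export
#' @examples
#' spectrum(variant_tbl("1", 1:3, c("C", "G", "C"), c("T", "A", "A")))
spectrum <- function(x) {
  v <- if (inherits(x, "variant_set")) x$variants else x
  classes <- if (nrow(v) > 0) {
    classify_substitution(v$ref, v$alt)
  } else {
    character()
  }
  counts <- table(factor(classes, levels = SUBSTITUTION_CLASSES))
  counts <- stats::setNames(as.integer(counts), SUBSTITUTION_CLASSES)
  total <- sum(counts)
  tr <- sum(counts[TRANSITION_CLASSES])
  tv <- total - tr
  structure(
    list(counts = counts, total = total,
         proportions = if (total > 0) counts / total else
           stats::setNames(rep(NA_real_, 6), SUBSTITUTION_CLASSES),
         tr_tv_ratio = if (tv > 0) tr / tv else NA_real_),
    class = "spectrum_summary"
  )
}

#' @export
print.spectrum_summary <- function(x, ...) {
  cat("<spectrum_summary>", x$total, "SNSs; Tr:Tv =",
      if (is.na(x$tr_tv_ratio)) "undefined" else
        format(x$tr_tv_ratio, digits = 3), "\n")
  print(x$counts)
  invisible(x)
}

#' Per-patient, per-subset spectrum table for a partitioned cohort
#'
#' @param partitions List of `trio_partition`s.
#' @param subsets Which subsets to tabulate.
#' @return Tibble with `patient_id`, `subset`, `class`, `count`,
#'   `proportion` (within patient-subset; `NA` for empty subsets).
#' @export
cohort_spectrum_table <- function(partitions,
                                  subsets = c("common", "unique_ptc",
                                              "unique_ant")) {
  rows <- list()
  for (p in partitions) {
    for (s in subsets) {
      sp <- spectrum(p[[s]])
      rows[[length(rows) + 1]] <- tibble(
        patient_id = p$patient_id, subset = s,
        class = SUBSTITUTION_CLASSES,
        count = unname(sp$counts),
        proportion = unname(sp$proportions)
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Fold-change of the Common subset's Tr:Tv over the unique subsets
#'
#' Older SNSs are transition-rich (spontaneous deamination of
#' 5-methylcytosine), so the Common subset is expected to carry the highest
#' Tr:Tv ratio of the three subsets. This computes, per patient,
#' `TrTv(common) / TrTv(unique_*)`, and the cohort means.
#'
#' @param partitions List of `trio_partition`s.
#' @return A list with `per_patient` (tibble `patient_id`,
#'   `trtv_common`, `trtv_unique_ptc`, `trtv_unique_ant`, `fold_ptc`,
#'   `fold_ant`) and `means` (named numeric `fold_ptc`, `fold_ant` over
#'   patients with defined ratios). Patients with an undefined Tr:Tv in any
#'   subset are excluded from the means with a warning.
#' @export
trtv_fold_change <- function(partitions) {
  per_patient <- dplyr::bind_rows(lapply(partitions, function(p) {
    tibble(
      patient_id = p$patient_id,
      trtv_common = spectrum(p$common)$tr_tv_ratio,
      trtv_unique_ptc = spectrum(p$unique_ptc)$tr_tv_ratio,
      trtv_unique_ant = spectrum(p$unique_ant)$tr_tv_ratio
    )
  }))
  per_patient$fold_ptc <- per_patient$trtv_common / per_patient$trtv_unique_ptc
  per_patient$fold_ant <- per_patient$trtv_common / per_patient$trtv_unique_ant
  incomplete <- !stats::complete.cases(
    per_patient[, c("fold_ptc", "fold_ant")])
  if (any(incomplete)) {
    warn(paste0("excluding ", sum(incomplete),
                " patient(s) with undefined Tr:Tv from fold-change means"))
  }
  list(
    per_patient = per_patient,
    means = c(fold_ptc = mean(per_patient$fold_ptc[!incomplete]),
              fold_ant = mean(per_patient$fold_ant[!incomplete]))
  )
}

#' Test for a shift of one substitution class between subsets
#'
#' The statistical unit is the per-patient proportion of `class_label`
#' within each subset (not pooled counts), matching cohort-level testing by
#' Welch's t. With two subsets a two-sided Welch two-sample t-test is
#' reported; with three or more, a one-way ANOVA (Welch-corrected via
#' [stats::oneway.test()]).
#'
#' @param partitions List of `trio_partition`s.
#' @param class_label One of the six strand-collapsed classes.
#' @param subsets Character vector (length >= 2) of subset names to compare;
#'   the reported `effect` for two subsets is
#'   `mean(subsets[1]) - mean(subsets[2])`.
#' @return A list: `per_patient` (tibble of proportions; patients with an
#'   empty subset are dropped from that subset), `means` (per subset),
#'   `effect`, `p_value`, and `test` (the underlying `htest`).
#' @export
spectrum_shift_test <- function(partitions, class_label,
                                subsets = c("unique_ptc", "common")) {
  stopifnot(class_label %in% SUBSTITUTION_CLASSES, length(subsets) >= 2)
  tab <- cohort_spectrum_table(partitions, subsets = subsets)
  tab <- tab[tab$class == class_label & !is.na(tab$proportion), ]
  n_per <- table(tab$subset)
  if (any(!(subsets %in% names(n_per))) || any(n_per[subsets] < 2)) {
    abort("spectrum_shift_test needs >= 2 patients with a non-empty spectrum per subset")
  }
  means <- named_vec(tapply(tab$proportion, tab$subset, mean)[subsets])
  if (length(subsets) == 2) {
    a <- tab$proportion[tab$subset == subsets[[1]]]
    b <- tab$proportion[tab$subset == subsets[[2]]]
    if (stats::var(a) + stats::var(b) == 0) {
      # degenerate: identical constant proportions on both sides
      test <- NULL
      p <- if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
    } else {
      test <- stats::t.test(a, b, var.equal = FALSE)
      p <- test$p.value
    }
    effect <- mean(a) - mean(b)
  } else {
    test <- stats::oneway.test(proportion ~ subset, data = tab,
                               var.equal = FALSE)
    p <- test$p.value
    effect <- max(means) - min(means)
  }
  list(per_patient = tab, means = means, effect = effect, p_value = p,
       test = test)
}
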