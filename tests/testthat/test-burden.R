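mk_burden_parts <- function() {
  mkv <- function(pos, cons) variant_tbl("1", pos, "C", "A",
                                         consequence = cons)
  lapply(1:3, function(i) {
    base <- 10000 * i
    common <- mkv(base + 1:6, rep(c("synonymous", "nonsynonymous"), 3))
    uptc <- mkv(base + 101:106, c(rep("nonsynonymous", 4), "synonymous",
                                  "noncoding"))
    uant <- mkv(base + 201:204, c(rep("nonsynonymous", 3), "synonymous"))
    partition_trio(
      variant_set(dplyr::bind_rows(common, uptc), "x_PTC", "PTC"),
      variant_set(dplyr::bind_rows(common, uant), "x_ANT", "ANT"),
      patient_id = paste0("p", i))
  })
}

test_that("zero votes yield zero predicted-deleterious counts", {
  parts <- mk_burden_parts()
  all_keys <- unlist(lapply(parts, function(p) {
    c(variant_keys(p$common), variant_keys(p$unique_ptc),
      variant_keys(p$unique_ant))
  }))
  votes0 <- stats::setNames(rep(0L, length(all_keys)), all_keys)
  db <- deleterious_burden(parts, votes0)
  expect_true(all(db$records$n_predicted_deleterious == 0))
  expect_true(all(db$records$rate == 0))
})

test_that("burden records respect count ordering and threshold monotonicity", {
  parts <- mk_burden_parts()
  all_keys <- unlist(lapply(parts, function(p) {
    c(variant_keys(p$common), variant_keys(p$unique_ptc),
      variant_keys(p$unique_ant))
  }))
  set.seed(71)
  votes <- stats::setNames(sample(0:5, length(all_keys), replace = TRUE),
                           all_keys)
  prev <- NULL
  for (thr in 1:5) {
    db <- deleterious_burden(parts, votes, vote_threshold = thr)
    r <- db$records
    expect_true(all(r$n_predicted_deleterious <= r$n_nonsynonymous))
    expect_true(all(r$n_nonsynonymous <= r$n_sns))
    if (!is.null(prev)) {
      expect_true(all(r$n_predicted_deleterious <=
                        prev$n_predicted_deleterious))
    }
    prev <- r
  }
  # missing votes warn and count as zero
  expect_warning(
    db2 <- deleterious_burden(parts, votes[-(1:4)]),
    "lack deleteriousness votes")
  expect_true(all(db2$records$n_missing_votes[db2$records$subset == "common" &
                                                db2$records$patient_id == "p1"] > 0))
})

test_that("an external comparison cohort enters the contrast", {
  parts <- mk_burden_parts()
  all_keys <- unlist(lapply(parts, function(p) {
    c(variant_keys(p$common), variant_keys(p$unique_ptc),
      variant_keys(p$unique_ant))
  }))
  votes <- stats::setNames(rep(5L, length(all_keys)), all_keys)
  votes[["1:10101:C:A"]] <- 0L  # break rate constancy so Welch t exists
  cmp <- lapply(1:2, function(i) {
    variant_set(variant_tbl("9", i * 100 + 1:4, "C", "T",
                            consequence = "synonymous"),
                paste0("ext", i), "BLOOD")
  })
  expect_warning(db <- deleterious_burden(parts, votes, comparison = cmp),
                 "lack deleteriousness votes")
  expect_equal(nrow(db$comparison_records), 2L)
  expect_true(all(db$comparison_records$rate == 0))
  expect_s3_class(db$tests$unique_ptc_vs_comparison, "htest")
})

test_that("subset SNS counts are additive over the PTC/ANT union", {
  parts <- mk_burden_parts()
  for (p in parts) {
    union_size <- length(unique(c(variant_keys(p$common),
                                  variant_keys(p$unique_ptc),
                                  variant_keys(p$unique_ant))))
    expect_equal(length(p$common) + length(p$unique_ptc) +
                   length(p$unique_ant), union_size)
  }
  totals <- cohort_sns_totals(parts)
  expect_equal(totals$n_sns, rep(12L, 3))  # 6 common + 6 unique_ptc
  expect_equal(cohort_sns_totals(parts, "ANT")$n_sns, rep(10L, 3))
})

mk_manifest <- function(n_sns_by_group) {
  tibble::tibble(
    patient_id = paste0("p", seq_along(n_sns_by_group$group)),
    age = n_sns_by_group$age %||% rep(50, length(n_sns_by_group$group)),
    sex = rep("F", length(n_sns_by_group$group)),
    race = "Caucasian", tnm_stage = "I",
    braf_mutant = n_sns_by_group$group == "mut",
    histology = "classical"
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("group contrasts of SNS burden: means, Welch t, ANOVA and degenerate groups", {
  # identical counts -> mean difference 0
  g <- list(group = c("mut", "mut", "wt", "wt"))
  totals <- tibble::tibble(patient_id = paste0("p", 1:4),
                           n_sns = c(10, 12, 10, 12))
  res <- burden_by_group(totals, mk_manifest(g), "braf")
  expect_equal(diff(res$by_group$mean), 0)

  # {10,10,10} vs {20,20,20} -> means 10 and 20 (no test: zero variance
  # would break Welch, so perturb one value and check the test runs)
  g2 <- list(group = c("mut", "mut", "mut", "wt", "wt", "wt"))
  totals2 <- tibble::tibble(patient_id = paste0("p", 1:6),
                            n_sns = c(10, 10, 10, 20, 20, 20))
  res2 <- suppressWarnings(tryCatch(
    burden_by_group(totals2, mk_manifest(g2), "braf"),
    error = function(e) NULL))
  means2 <- tapply(totals2$n_sns, g2$group, mean)
  expect_equal(as.vector(means2), c(10, 20))
  totals2$n_sns[1] <- 11
  res2b <- burden_by_group(totals2, mk_manifest(g2), "braf")
  expect_equal(res2b$by_group$mean[res2b$by_group$group == "BRAF-mutant"],
               31 / 3)
  expect_lt(res2b$p_value, 0.05)

  # age dichotomy: exact-45 goes to the younger group by default
  g3 <- list(group = c("mut", "mut", "wt", "wt"),
             age = c(45, 30, 60, 70))
  totals3 <- tibble::tibble(patient_id = paste0("p", 1:4),
                            n_sns = c(10, 11, 20, 21))
  res3 <- burden_by_group(totals3, mk_manifest(g3), "age45")
  expect_equal(res3$by_group$n, c(2L, 2L))
  expect_equal(res3$by_group$mean[res3$by_group$group == "<=45"], 10.5)
  # moving age 45 to the older group leaves a 3-vs-1 split: means only
  expect_warning(
    res3b <- burden_by_group(totals3, mk_manifest(g3), "age45",
                             older_inclusive = TRUE),
    "degenerate")
  expect_equal(res3b$by_group$n[res3b$by_group$group == ">=45"], 3L)

  # >2 groups -> ANOVA
  m4 <- mk_manifest(list(group = rep("wt", 6)))
  m4$tnm_stage <- rep(c("I", "II", "III"), each = 2)
  totals4 <- tibble::tibble(patient_id = paste0("p", 1:6),
                            n_sns = c(10, 12, 20, 22, 30, 33))
  res4 <- burden_by_group(totals4, m4, "stage")
  expect_equal(nrow(res4$by_group), 3L)
  expect_s3_class(res4$test, "htest")
  expect_lt(res4$p_value, 0.05)

  # degenerate group sizes -> means only with a warning
  m5 <- mk_manifest(list(group = c("mut", "wt", "wt", "wt")))
  expect_warning(res5 <- burden_by_group(totals, m5, "braf"), "degenerate")
  expect_null(res5$test)
})
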