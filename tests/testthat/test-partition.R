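test_that("identical and disjoint signatures partition as expected", {
  p <- make_vs(1:3, "p_PTC", "PTC")
  a <- make_vs(1:3, "p_ANT", "ANT")
  tp <- partition_trio(p, a)
  expect_equal(length(tp$common), 3L)
  expect_equal(length(tp$unique_ptc), 0L)
  expect_equal(length(tp$unique_ant), 0L)
  expect_equal(tp$shared_fraction_ptc, 1.0)

  tp2 <- partition_trio(make_vs(1, "p_PTC", "PTC"),
                        make_vs(2, "p_ANT", "ANT"))
  expect_equal(length(tp2$common), 0L)
  expect_equal(tp2$shared_fraction_ptc, 0.0)
})

test_that("the worked three-way example with blood matches hand enumeration", {
  tp <- partition_trio(make_vs(1:5, "p_PTC", "PTC"),
                       make_vs(3:8, "p_ANT", "ANT"),
                       blood = make_vs(c(3, 4, 9), "p_BLOOD", "BLOOD"))
  expect_setequal(variant_keys(tp$common), variant_keys(make_vs(3:5)))
  expect_setequal(variant_keys(tp$unique_ptc), variant_keys(make_vs(1:2)))
  expect_setequal(variant_keys(tp$unique_ant), variant_keys(make_vs(6:8)))
  expect_equal(tp$blood_overlap,
               c(common = 2 / 3, unique_ptc = 0, unique_ant = 0))
})

test_that("mismatched patient ids are fatal unless overridden", {
  expect_error(partition_trio(make_vs(1:3, "p1_PTC", "PTC"),
                              make_vs(1:3, "p2_ANT", "ANT")),
               "different patients")
  tp <- partition_trio(make_vs(1:3, "p1_PTC", "PTC"),
                       make_vs(1:3, "p2_ANT", "ANT"), patient_id = "pX")
  expect_equal(tp$patient_id, "pX")
})

test_that("partition obeys conservation, disjointness and mirror symmetry on random trios", {
  set.seed(41)
  for (rep in 1:25) {
    ip <- sample.int(100, sample(0:60, 1))
    ia <- sample.int(100, sample(1:60, 1))
    p <- make_vs(ip, "q_PTC", "PTC")
    a <- make_vs(ia, "q_ANT", "ANT")
    tp <- partition_trio(p, a)
    # per-key membership oracle
    expect_setequal(variant_keys(tp$common), variant_keys(make_vs(intersect(ip, ia))))
    expect_setequal(variant_keys(tp$unique_ptc), variant_keys(make_vs(setdiff(ip, ia))))
    expect_setequal(variant_keys(tp$unique_ant), variant_keys(make_vs(setdiff(ia, ip))))
    # conservation
    expect_equal(length(tp$common) + length(tp$unique_ptc), length(p))
    expect_equal(length(tp$common) + length(tp$unique_ant), length(a))
    # pairwise disjoint
    expect_length(intersect(variant_keys(tp$common), variant_keys(tp$unique_ptc)), 0)
    expect_length(intersect(variant_keys(tp$unique_ptc), variant_keys(tp$unique_ant)), 0)
    # mirror image
    tm <- partition_trio(a, p, patient_id = "q")
    expect_setequal(variant_keys(tm$common), variant_keys(tp$common))
    expect_setequal(variant_keys(tm$unique_ptc), variant_keys(tp$unique_ant))
    if (length(p) > 0) {
      expect_equal(tp$shared_fraction_ptc, length(tp$common) / length(p))
    } else {
      expect_true(is.na(tp$shared_fraction_ptc))
    }
  }
})

make_part <- function(idx_p, idx_a, pid, idx_b = NULL) {
  partition_trio(make_vs(idx_p, paste0(pid, "_PTC"), "PTC"),
                 make_vs(idx_a, paste0(pid, "_ANT"), "ANT"),
                 blood = if (is.null(idx_b)) NULL else
                   make_vs(idx_b, paste0(pid, "_BLOOD"), "BLOOD"),
                 patient_id = pid)
}

test_that("pairwise overlap matches brute-force counting and its edge cases", {
  # identical common subsets -> all off-diagonal entries 1
  same <- list(make_part(1:5, 1:5, "a"), make_part(1:5, 1:5, "b"))
  ov <- pairwise_overlap(same, "common")
  expect_true(all(ov$matrix[upper.tri(ov$matrix) | lower.tri(ov$matrix)] == 1))
  expect_true(all(is.na(diag(ov$matrix))))

  # pairwise-disjoint subsets -> cohort mean 0
  disj <- list(make_part(1:5, 1:5, "a"), make_part(6:9, 6:9, "b"),
               make_part(11:13, 11:13, "c"))
  expect_equal(pairwise_overlap(disj, "common")$cohort_mean, 0)

  # 4 constructed patients vs brute-force pairwise counting
  idx <- list(a = 1:10, b = 5:14, c = c(1, 5, 20), d = 21:24)
  parts <- lapply(names(idx), function(pid) make_part(idx[[pid]], idx[[pid]], pid))
  ov4 <- pairwise_overlap(parts, "common")
  for (i in names(idx)) for (j in names(idx)) {
    if (i == j) next
    expect_equal(ov4$matrix[i, j],
                 length(intersect(idx[[i]], idx[[j]])) / length(idx[[i]]))
  }
  expect_true(all(ov4$matrix >= 0 & ov4$matrix <= 1, na.rm = TRUE))
  # jaccard alternative is symmetric
  ovj <- pairwise_overlap(parts, "common", metric = "jaccard")
  expect_equal(ovj$matrix["a", "b"], ovj$matrix["b", "a"])
  expect_equal(ovj$matrix["a", "b"], 6 / 14)
})

test_that("empty subsets give undefined overlap rows, excluded from means", {
  parts <- list(make_part(1:4, 5:8, "a"),   # unique_ptc = 1:4
                make_part(1:4, 1:4, "b"),   # unique_ptc empty
                make_part(2:5, 6:9, "c"))
  ov <- pairwise_overlap(parts, "unique_ptc")
  expect_true(all(is.na(ov$matrix["b", ])))
  expect_true(is.na(ov$patient_means[["b"]]))
  expect_false(is.na(ov$cohort_mean))
})

test_that("blood concordance summarises per-subset fractions with a Welch contrast", {
  # blood equal to common and disjoint from uniques -> means (1, 0, 0)
  parts <- list(make_part(1:6, c(1:4, 7, 8), "a", idx_b = 1:4),
                make_part(10:15, c(10:13, 30, 31), "b", idx_b = 10:13))
  bc <- blood_concordance_summary(parts)
  expect_equal(unname(bc$means), c(1, 0, 0))
  expect_equal(bc$p_value, 0)  # perfect separation, constant on both sides

  # single blood patient: means computed, test absent
  one <- list(make_part(1:6, c(1:4, 7, 8), "a", idx_b = 1:4),
              make_part(10:15, c(10:13, 30, 31), "b"))
  expect_warning(bc1 <- blood_concordance_summary(one), "fewer than 2")
  expect_null(bc1$test)
  expect_equal(unname(bc1$means), c(1, 0, 0))
})
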