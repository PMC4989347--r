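write_raw_vcf <- function(body, path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"),
    body
  ), path)
  path
}

test_that("VCF ingestion deduplicates, skips non-SNS records and decomposes multi-allelics", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_raw_vcf(c(
    "1\t100\t.\tC\tT\t50\tPASS\tDP=30",
    "1\t100\t.\tC\tT\t50\tPASS\tDP=30",
    "1\t200\t.\tG\tA\t60\tPASS\tDP=25",
    "1\t300\t.\tCT\tC\t40\tPASS\tDP=20"
  ), path)
  vs <- read_variant_set(path, "s1", "PTC")
  expect_s3_class(vs, "variant_set")
  expect_equal(length(vs), 2L)
  expect_setequal(variant_keys(vs), c("1:100:C:T", "1:200:G:A"))
  expect_equal(attr(vs, "n_skipped_non_sns"), 1L)

  path2 <- withr::local_tempfile(fileext = ".vcf")
  write_raw_vcf("1\t500\t.\tA\tC,G\t50\tPASS\tDP=30", path2)
  vs2 <- read_variant_set(path2, "s2", "ANT")
  expect_setequal(variant_keys(vs2), c("1:500:A:C", "1:500:A:G"))
  expect_equal(vs2$variants$depth, c(30L, 30L))
})

test_that("ingestion failure modes: malformed lines name the line, empty files warn", {
  bad <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2", "#CHROM\tPOS", "1\t100\tC"), bad)
  expect_error(read_variant_set(bad, "s", "PTC"), "line 3")
  notvcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines("chrom\tpos", notvcf)
  expect_error(read_variant_set(notvcf, "s", "PTC"), "fileformat")
  expect_error(read_variant_set(withr::local_tempfile(), "s", "PTC"),
               "no such file")
  empty <- withr::local_tempfile(fileext = ".vcf")
  write_raw_vcf(character(), empty)
  expect_warning(vs <- read_variant_set(empty, "s", "PTC"), "no variant")
  expect_equal(length(vs), 0L)
})

test_that("write-then-read round-trips keys and annotations, independent of row order", {
  set.seed(11)
  for (rep in 1:5) {
    v <- rand_variant_tbl(80, with_annots = TRUE)
    v$consequence <- sample(c("synonymous", "nonsynonymous", "noncoding"),
                            nrow(v), replace = TRUE)
    v$gene <- sample(c("G1", "G2", NA), nrow(v), replace = TRUE)
    vs <- variant_set(v, "rt", "PTC")
    path <- withr::local_tempfile(fileext = ".vcf")
    write_variant_set(vs, path)
    back <- read_variant_set(path, "rt", "PTC")
    expect_setequal(variant_keys(back), variant_keys(vs))
    # annotations survive: compare after aligning on keys
    m <- match(variant_keys(vs), variant_keys(back))
    expect_equal(back$variants$depth[m], vs$variants$depth)
    expect_equal(back$variants$qual[m], vs$variants$qual)
    expect_equal(back$variants$gene[m], vs$variants$gene)
    # shuffled file body yields the identical set
    lines <- readLines(path)
    hdr <- startsWith(lines, "#")
    shuffled <- withr::local_tempfile(fileext = ".vcf")
    writeLines(c(lines[hdr], sample(lines[!hdr])), shuffled)
    expect_setequal(variant_keys(read_variant_set(shuffled, "rt", "PTC")),
                    variant_keys(vs))
  }
})

test_that("chr prefix stripping is opt-in", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_raw_vcf("chr1\t100\t.\tC\tT\t50\tPASS\t.", path)
  expect_equal(read_variant_set(path, "s", "PTC")$variants$chrom, "chr1")
  expect_equal(read_variant_set(path, "s", "PTC",
                                strip_chr_prefix = TRUE)$variants$chrom, "1")
})

test_that("exclusion lists: TSV dedup, empty file, and VCF/TSV dialect equality", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("1\t100\tC\tT", "1\t200\tG\tA", "1\t100\tC\tT"), tsv)
  keys <- read_exclusion_list(tsv)
  expect_setequal(keys, c("1:100:C:T", "1:200:G:A"))

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(), empty)
  expect_length(read_exclusion_list(empty), 0L)

  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_raw_vcf(c("1\t100\t.\tC\tT\t.\tPASS\t.", "1\t200\t.\tG\tA\t.\tPASS\t."),
                vcf)
  expect_setequal(read_exclusion_list(vcf), keys)

  headered <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\talt", "1\t100\tC\tT"), headered)
  expect_equal(read_exclusion_list(headered), "1:100:C:T")

  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1\t100\tC\tT", "just-one-field"), bad)
  expect_error(read_exclusion_list(bad), "neither VCF nor 4-column")
})

test_that("deleteriousness votes aggregate predictor calls and round-trip", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "chrom\tpos\tref\talt\tpp2\tmt\tsift\trsvm\tlr",
    "1\t10\tC\tT\tD\tD\tT\tD\tT",
    "1\t20\tG\tA\tT\tT\tT\tT\tT",
    "1\t30\tA\tG\t1\t0\t1\t.\t1"
  ), tsv)
  votes <- read_deleteriousness_table(tsv)
  expect_equal(unname(votes[c("1:10:C:T", "1:20:G:A", "1:30:A:G")]),
               c(3L, 0L, 3L))

  set.seed(4)
  orig <- stats::setNames(sample(0:5, 40, replace = TRUE),
                          paste("1", 1:40, "C", "T", sep = ":"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_deleteriousness_table(orig, path)
  expect_identical(read_deleteriousness_table(path)[names(orig)], orig)

  toomany <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste(c("chrom", "pos", "ref", "alt", paste0("p", 1:6)),
                     collapse = "\t"),
               paste(c("1", "10", "C", "T", rep("D", 6)), collapse = "\t")),
             toomany)
  expect_error(read_deleteriousness_table(toomany), "at most 5")
})

test_that("manifests load from YAML and TSV with path checking and unique ids", {
  dir <- withr::local_tempdir()
  vs <- make_vs(1:5)
  for (fn in c("p1_t.vcf", "p1_n.vcf", "p2_t.vcf", "p2_n.vcf")) {
    write_variant_set(vs, file.path(dir, fn))
  }
  yml <- file.path(dir, "m.yaml")
  yaml::write_yaml(list(patients = list(
    list(patient_id = "p1", ptc_path = "p1_t.vcf", ant_path = "p1_n.vcf",
         age = 52, sex = "F", braf_mutant = TRUE),
    list(patient_id = "p2", ptc_path = "p2_t.vcf", ant_path = "p2_n.vcf",
         age = 31, sex = "M", braf_mutant = FALSE)
  )), yml)
  mf <- read_manifest(yml)
  expect_equal(mf$patient_id, c("p1", "p2"))
  expect_true(all(file.exists(mf$ptc_path)))
  expect_true(is.na(mf$blood_path[1]))

  tsv <- file.path(dir, "m.tsv")
  utils::write.table(
    data.frame(patient_id = c("p1", "p2"),
               ptc_path = c("p1_t.vcf", "p2_t.vcf"),
               ant_path = c("p1_n.vcf", "p2_n.vcf"),
               age = c(52, 31), sex = c("F", "M"),
               braf_mutant = c(TRUE, FALSE)),
    tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  mf2 <- read_manifest(tsv)
  expect_equal(mf2$age, mf$age)

  dup <- file.path(dir, "dup.yaml")
  yaml::write_yaml(list(patients = list(
    list(patient_id = "p1", ptc_path = "p1_t.vcf", ant_path = "p1_n.vcf"),
    list(patient_id = "p1", ptc_path = "p2_t.vcf", ant_path = "p2_n.vcf")
  )), dup)
  expect_error(read_manifest(dup), "not unique")

  missing <- file.path(dir, "gone.yaml")
  yaml::write_yaml(list(patients = list(
    list(patient_id = "p1", ptc_path = "nope.vcf", ant_path = "p1_n.vcf")
  )), missing)
  expect_error(read_manifest(missing), "missing file")
})
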