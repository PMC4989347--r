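#' Read a per-sample SNS call set from VCF
#'
#' Ingests a VCF 4.x file into a [variant_set()]. Only single-nucleotide
#' records are kept: multi-allelic lines are decomposed into one variant per
#' alternate base, indels and MNVs are counted and skipped, and the result is
#' deduplicated by variant key. Genotype fields are ignored — presence of a
#' record is presence of the SNS in the sample.
#'
#' Recognised INFO keys: `DP` (read depth), `GENE` (symbol) and `CSQ`
#' (coding consequence); anything else is ignored. The `QUAL` column is kept
#' as the variant quality score.
#'
#' @param path Path to a VCF file.
#' @param sample_id Sample identifier to stamp on the set.
#' @param tissue `"PTC"`, `"ANT"` or `"BLOOD"`.
#' @param strip_chr_prefix If `TRUE`, a leading `"chr"` is removed from
#'   chromosome names on load (dialect tolerance; default `FALSE`, names are
#'   otherwise compared as exact strings).
#' @return A [variant_set()]. The number of skipped non-SNS records is
#'   attached as attribute `n_skipped_non_sns`.
#' @export
read_variant_set <- function(path, sample_id, tissue = c("PTC", "ANT", "BLOOD"),
                             strip_chr_prefix = FALSE) {
  tissue <- match.arg(tissue)
  check_vcf_lines(path)
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) abort(paste0("failed to parse VCF '", path, "': ",
                                     conditionMessage(e)))
  )
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    warn(paste0("VCF '", path, "' contains no variant records"))
    vs <- variant_set(empty_variant_tbl(), sample_id, tissue)
    attr(vs, "n_skipped_non_sns") <- 0L
    return(vs)
  }
  info <- fix$INFO
  df <- tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    qual = suppressWarnings(as.numeric(fix$QUAL)),
    depth = suppressWarnings(as.integer(info_field(info, "DP"))),
    gene = info_field(info, "GENE"),
    consequence = info_field(info, "CSQ")
  )
  df$consequence[is.na(df$consequence)] <- "unknown"
  # decompose multi-allelic records: one row per alternate allele
  df <- tidyr::separate_rows(df, "alt", sep = ",")
  is_sns <- nchar(df$ref) == 1L & nchar(df$alt) == 1L &
    df$ref %in% DNA_BASES & df$alt %in% DNA_BASES & df$ref != df$alt
  n_skipped <- sum(!is_sns)
  df <- df[is_sns, , drop = FALSE]
  if (strip_chr_prefix) df$chrom <- sub("^chr", "", df$chrom)
  df$deleterious_votes <- NA_integer_
  vs <- variant_set(df, sample_id, tissue)
  attr(vs, "n_skipped_non_sns") <- n_skipped
  vs
}

# Cheap structural validation so parse failures report a line number.
check_vcf_lines <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || !startsWith(lines[[1]], "##fileformat=VCF")) {
    abort(paste0("'", path, "' is not a VCF: line 1 lacks ##fileformat=VCF"))
  }
  body <- which(!startsWith(lines, "#"))
  bad <- body[vapply(strsplit(lines[body], "\t", fixed = TRUE), length,
                     integer(1)) < 8L]
  if (length(bad) > 0) {
    abort(paste0("malformed VCF record in '", path, "' at line ", bad[[1]],
                 " (fewer than 8 tab-separated fields)"))
  }
  invisible(TRUE)
}

info_field <- function(info, key) {
  pat <- paste0("(?:^|;)", key, "=([^;]*)")
  m <- regmatches(info, regexpr(pat, info, perl = TRUE))
  out <- rep(NA_character_, length(info))
  hit <- grepl(pat, info, perl = TRUE)
  out[hit] <- sub(pat, "\\1", m, perl = TRUE)
  out
}

#' Write a variant set as VCF
#'
#' Emits a minimal, valid VCF 4.2 text file carrying `QUAL` plus the INFO
#' keys `DP`, `GENE` and `CSQ` that [read_variant_set()] understands, so
#' write-then-read round-trips the variant key set and annotations.
#'
#' @param vs A [variant_set()].
#' @param path Output path.
#' @param contigs Optional named integer vector of contig lengths for the
#'   header.
#' @return `path`, invisibly.
#' @export
write_variant_set <- function(vs, path, contigs = NULL) {
  stopifnot(inherits(vs, "variant_set"))
  v <- vs$variants
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=somaphyl",
    if (!is.null(contigs)) {
      sprintf("##contig=<ID=%s,length=%d>", names(contigs),
              as.integer(contigs))
    },
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Coding consequence\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t")
  )
  if (nrow(v) > 0) {
    ord <- order(v$chrom, v$pos, v$ref, v$alt)
    v <- v[ord, , drop = FALSE]
    info <- paste0(
      ifelse(is.na(v$depth), "", paste0("DP=", v$depth)),
      ifelse(is.na(v$gene), "", paste0(";GENE=", v$gene)),
      ifelse(is.na(v$consequence) | v$consequence == "unknown", "",
             paste0(";CSQ=", v$consequence))
    )
    info <- sub("^;", "", info)
    info[info == ""] <- "."
    body <- paste(v$chrom, v$pos, ".", v$ref, v$alt,
                  ifelse(is.na(v$qual), ".", format(v$qual, trim = TRUE)),
                  "PASS", info, sep = "\t")
  } else {
    body <- character()
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a known-variant exclusion list
#'
#' Reads a dbSNP-style list of variant keys to exclude, either as a VCF or
#' as a 4-column TSV (`chrom`, `pos`, `ref`, `alt`; a header row is
#' tolerated). Positions are 1-based in both dialects, so the two encodings
#' of the same records yield the same key set.
#'
#' @param path Path to the list.
#' @return Character vector of unique variant keys (`"chrom:pos:ref:alt"`).
#' @export
read_exclusion_list <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(character())
  if (startsWith(lines[[1]], "##fileformat=VCF")) {
    vs <- read_variant_set(path, sample_id = "exclusion", tissue = "PTC")
    return(variant_keys(vs))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- vapply(fields, length, integer(1))
  if (any(n_fields < 4L)) {
    abort(paste0("exclusion list '", path, "' is neither VCF nor 4-column ",
                 "TSV (line ", which(n_fields < 4L)[[1]], " has ",
                 min(n_fields), " fields)"))
  }
  df <- do.call(rbind, fields)
  # drop a header row such as "chrom\tpos\tref\talt"
  if (suppressWarnings(is.na(as.integer(df[1, 2])))) {
    df <- df[-1, , drop = FALSE]
  }
  if (nrow(df) == 0) return(character())
  pos <- suppressWarnings(as.integer(df[, 2]))
  if (anyNA(pos)) {
    abort(paste0("exclusion list '", path, "': non-integer position at data ",
                 "row ", which(is.na(pos))[[1]]))
  }
  unique(paste(df[, 1], pos, df[, 3], df[, 4], sep = ":"))
}

#' Read per-variant deleteriousness predictor calls
#'
#' Reads a TSV of per-predictor damaging calls — one row per variant, columns
#' `chrom`, `pos`, `ref`, `alt` followed by up to five predictor columns
#' coded `D`/`T` or `1`/`0` (missing or `.` counts as non-damaging) — and
#' aggregates them to a vote count per variant, the form consumed by the
#' burden summaries.
#'
#' @param path Path to the TSV (header row required).
#' @return Named integer vector of votes (0-5), named by variant key.
#' @export
read_deleteriousness_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(df))) {
    abort("deleteriousness table must have columns chrom, pos, ref, alt")
  }
  pred_cols <- setdiff(names(df), need)
  if (length(pred_cols) > 5L) {
    abort(paste0("deleteriousness table has ", length(pred_cols),
                 " predictor columns; at most 5 supported"))
  }
  if (nrow(df) == 0) return(stats::setNames(integer(), character()))
  damaging <- vapply(pred_cols, function(cn) {
    df[[cn]] %in% c("D", "1")
  }, logical(nrow(df)))
  votes <- as.integer(rowSums(matrix(damaging, nrow = nrow(df))))
  keys <- paste(df$chrom, as.integer(df$pos), df$ref, df$alt, sep = ":")
  keep <- !duplicated(keys)
  stats::setNames(votes[keep], keys[keep])
}

#' Write a deleteriousness predictor table
#'
#' Inverse of [read_deleteriousness_table()]: expands vote counts into five
#' predictor columns (`pred1`..`pred5`), the first `votes` of which are `D`.
#'
#' @param votes Named integer vector (0-5), named by variant key.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_deleteriousness_table <- function(votes, path) {
  stopifnot(all(votes >= 0 & votes <= 5))
  keys <- names(votes)
  parts <- strsplit(keys, ":", fixed = TRUE)
  df <- data.frame(
    chrom = vapply(parts, `[[`, "", 1),
    pos = vapply(parts, `[[`, "", 2),
    ref = vapply(parts, `[[`, "", 3),
    alt = vapply(parts, `[[`, "", 4),
    stringsAsFactors = FALSE
  )
  for (i in 1:5) {
    df[[paste0("pred", i)]] <- ifelse(votes >= i, "D", "T")
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cohort manifest
#'
#' The manifest maps each patient to their per-tissue VCFs and clinical
#' covariates (age, sex, race, TNM stage, BRAF status, histology). Two
#' dialects are accepted: YAML with a top-level `patients:` list, or a TSV
#' with one row per patient. Relative VCF paths are resolved against the
#' manifest's directory.
#'
#' @param path Path to a `.yaml`/`.yml` or `.tsv` manifest.
#' @param check_paths If `TRUE` (default) referenced sample files must exist.
#' @return A tibble with columns `patient_id`, `ptc_path`, `ant_path`,
#'   `blood_path` (`NA` if absent), `age`, `sex`, `race`, `tnm_stage`,
#'   `braf_mutant`, `histology`.
#' @export
read_manifest <- function(path, check_paths = TRUE) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  base <- dirname(path)
  if (grepl("\\.ya?ml$", path)) {
    y <- yaml::read_yaml(path)
    if (is.null(y$patients)) abort("YAML manifest lacks a 'patients' list")
    rows <- lapply(y$patients, function(p) {
      tibble(
        patient_id = as.character(p$patient_id),
        ptc_path = as.character(p$ptc_path),
        ant_path = as.character(p$ant_path),
        blood_path = if (is.null(p$blood_path)) NA_character_ else
          as.character(p$blood_path),
        age = as.numeric(p$age %||% NA),
        sex = as.character(p$sex %||% NA),
        race = as.character(p$race %||% NA),
        tnm_stage = as.character(p$tnm_stage %||% NA),
        braf_mutant = as.logical(p$braf_mutant %||% NA),
        histology = as.character(p$histology %||% NA)
      )
    })
    mf <- dplyr::bind_rows(rows)
  } else {
    mf <- as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE))
    if (!"blood_path" %in% names(mf)) mf$blood_path <- NA_character_
    mf$blood_path[mf$blood_path %in% c("", ".")] <- NA_character_
    mf$braf_mutant <- as.logical(mf$braf_mutant)
  }
  if (anyDuplicated(mf$patient_id)) {
    abort("manifest patient_ids are not unique")
  }
  for (col in c("ptc_path", "ant_path", "blood_path")) {
    rel <- !is.na(mf[[col]]) & !file.exists(mf[[col]])
    mf[[col]][rel] <- file.path(base, mf[[col]][rel])
    if (check_paths) {
      gone <- !is.na(mf[[col]]) & !file.exists(mf[[col]])
      if (any(gone)) {
        abort(paste0("manifest references missing file(s): ",
                     toString(utils::head(mf[[col]][gone], 3))))
      }
    }
  }
  mf
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a full cohort from its manifest
#'
#' Reads every per-sample VCF named in the manifest into [variant_set()]s.
#'
#' @inheritParams read_manifest
#' @param strip_chr_prefix Passed to [read_variant_set()].
#' @return An object of class `sns_cohort`: a list with `manifest` (tibble)
#'   and `patients`, a named list per patient of `list(ptc, ant, blood)`
#'   variant sets (`blood` may be `NULL`).
#' @export
load_cohort <- function(path, strip_chr_prefix = FALSE) {
  mf <- read_manifest(path)
  patients <- lapply(seq_len(nrow(mf)), function(i) {
    pid <- mf$patient_id[[i]]
    list(
      ptc = read_variant_set(mf$ptc_path[[i]], paste0(pid, "_PTC"), "PTC",
                             strip_chr_prefix),
      ant = read_variant_set(mf$ant_path[[i]], paste0(pid, "_ANT"), "ANT",
                             strip_chr_prefix),
      blood = if (is.na(mf$blood_path[[i]])) NULL else
        read_variant_set(mf$blood_path[[i]], paste0(pid, "_BLOOD"), "BLOOD",
                         strip_chr_prefix)
    )
  })
  names(patients) <- mf$patient_id
  structure(list(manifest = mf, patients = patients), class = "sns_cohort")
}

#' @export
print.sns_cohort <- function(x, ...) {
  n_blood <- sum(!vapply(x$patients, function(p) is.null(p$blood), logical(1)))
  cat(sprintf("<sns_cohort> %d patients (%d with blood)\n",
              length(x$patients), n_blood))
  invisible(x)
}
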