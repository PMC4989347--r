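#' @importFrom rlang .data abort warn
#' @importFrom tibble tibble as_tibble
NULL

DNA_BASES <- c("A", "C", "G", "T")

CONSEQUENCE_LEVELS <- c("synonymous", "nonsynonymous", "stopgain",
                        "stoploss", "noncoding", "unknown")

TISSUE_LEVELS <- c("PTC", "ANT", "BLOOD")

#' Build a table of single-nucleotide substitutions
#'
#' The elementary record of the package: one single-nucleotide substitution
#' (SNS), identified by `(chrom, pos, ref, alt)` in 1-based VCF coordinates,
#' optionally carrying quality/coverage evidence and annotations.
#'
#' @param chrom Chromosome names (character, kept verbatim).
#' @param pos 1-based positions (integer-like, `>= 1`).
#' @param ref,alt Single reference/alternate bases in `A,C,G,T`; `ref != alt`.
#' @param qual Optional non-negative variant quality scores (`NA` = absent).
#' @param depth Optional non-negative read depths (`NA` = absent).
#' @param gene Optional gene symbols.
#' @param consequence Coding consequence, one of `r toString(CONSEQUENCE_LEVELS)`.
#' @param deleterious_votes Optional integer 0-5: number of upstream protein
#'   impact predictors calling the variant damaging.
#'
#' @return A tibble with one validated row per substitution.
#' @export
#' @examples
#' variant_tbl(chrom = "1", pos = c(100, 200), ref = c("C", "G"),
#'             alt = c("T", "A"))
variant_tbl <- function(chrom = character(), pos = integer(),
                        ref = character(), alt = character(),
                        qual = NA_real_, depth = NA_integer_,
                        gene = NA_character_,
                        consequence = "unknown",
                        deleterious_votes = NA_integer_) {
  out <- tibble(
    chrom = as.character(chrom),
    pos = as.integer(pos),
    ref = as.character(ref),
    alt = as.character(alt),
    qual = as.numeric(qual),
    depth = as.integer(depth),
    gene = as.character(gene),
    consequence = as.character(consequence),
    deleterious_votes = as.integer(deleterious_votes)
  )
  validate_variants(out)
  out
}

validate_variants <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("variant table lacks column(s): ",
                 toString(missing_cols)))
  }
  if (nrow(x) == 0) return(invisible(x))
  if (anyNA(x$pos) || any(x$pos < 1L)) {
    abort("variant positions must be integers >= 1")
  }
  bad_base <- !(x$ref %in% DNA_BASES) | !(x$alt %in% DNA_BASES)
  if (any(bad_base)) {
    abort(paste0("non-SNS or non-ACGT alleles at row(s) ",
                 toString(utils::head(which(bad_base), 5))))
  }
  if (any(x$ref == x$alt)) {
    abort("ref and alt must differ (SNS only)")
  }
  if ("qual" %in% names(x) && any(x$qual < 0, na.rm = TRUE)) {
    abort("qual must be non-negative")
  }
  if ("depth" %in% names(x) && any(x$depth < 0, na.rm = TRUE)) {
    abort("depth must be non-negative")
  }
  if ("deleterious_votes" %in% names(x) &&
      any(x$deleterious_votes < 0 | x$deleterious_votes > 5, na.rm = TRUE)) {
    abort("deleterious_votes must lie in 0..5")
  }
  invisible(x)
}

#' Variant identity keys
#'
#' Variant identity throughout the package is the string
#' `"chrom:pos:ref:alt"`; no strand normalisation is applied at this level
#' (strand collapsing happens only when classifying substitution spectra).
#'
#' @param x A variant table (or `variant_set`).
#' @return Character vector of keys, one per row.
#' @export
variant_keys <- function(x) {
  if (inherits(x, "variant_set")) x <- x$variants
  if (nrow(x) == 0) return(character())
  paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
}

#' The deduplicated SNS signature of one tissue sample
#'
#' A `variant_set` couples a validated variant table with its sample identity
#' and tissue label. Rows are deduplicated by variant key: presence of a
#' record means presence of that substitution in the sample, so the set is
#' the sample's SNS *signature*, not its genotype calls.
#'
#' @param variants A variant table as from [variant_tbl()].
#' @param sample_id Sample identifier.
#' @param tissue One of `"PTC"`, `"ANT"`, `"BLOOD"`.
#' @return An object of class `variant_set` with elements `variants`
#'   (tibble), `sample_id`, `tissue`.
#' @export
#' @examples
#' vs <- variant_set(variant_tbl("1", c(1, 1, 5), c("C", "C", "G"),
#'                               c("T", "T", "A")),
#'                   sample_id = "P1_T", tissue = "PTC")
#' nrow(vs$variants)  # duplicate collapsed -> 2
variant_set <- function(variants, sample_id, tissue = c("PTC", "ANT", "BLOOD")) {
  tissue <- match.arg(tissue)
  validate_variants(variants)
  variants <- as_tibble(variants)
  keys <- paste(variants$chrom, variants$pos, variants$ref, variants$alt,
                sep = ":")
  variants <- variants[!duplicated(keys), , drop = FALSE]
  structure(
    list(variants = variants, sample_id = as.character(sample_id),
         tissue = tissue),
    class = "variant_set"
  )
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("<variant_set> sample %s (%s): %d SNSs\n",
              x$sample_id, x$tissue, nrow(x$variants)))
  invisible(x)
}

#' @export
length.variant_set <- function(x) nrow(x$variants)

empty_variant_tbl <- function() variant_tbl()

# tapply returns a 1-d array; flatten to a plain named vector
named_vec <- function(x) stats::setNames(as.vector(x), names(x))

# Welch t that degrades gracefully: NULL when a group is too small or both
# groups are constant (no t statistic exists)
safe_welch <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) return(NULL)
  if (stats::var(a) + stats::var(b) == 0) return(NULL)
  stats::t.test(a, b, var.equal = FALSE)
}

# Subset a variant_set to the rows whose keys are in `keys`.
variant_set_subset <- function(vs, keys) {
  keep <- variant_keys(vs) %in% keys
  variant_set(vs$variants[keep, , drop = FALSE], vs$sample_id, vs$tissue)
}
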