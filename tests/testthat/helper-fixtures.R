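# Deterministic key universe: index i (>= 0) maps to one fixed SNS key so
# set-algebra tests can reason about integer index sets.
key_tbl <- function(idx) {
  if (length(idx) == 0) return(variant_tbl())
  refs <- c("A", "C", "G", "T")[(idx %% 4) + 1]
  alts <- c("G", "T", "A", "C")[(idx %% 4) + 1]  # always a transition
  variant_tbl(chrom = "1", pos = idx + 10, ref = refs, alt = alts)
}

make_vs <- function(idx, sample_id = "s_PTC", tissue = "PTC") {
  variant_set(key_tbl(idx), sample_id, tissue)
}

# Random variant table over a small locus space, for round-trip and
# filter-oracle properties.
rand_variant_tbl <- function(n, with_annots = FALSE) {
  pos <- sample.int(5000, n)
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                character(1), USE.NAMES = FALSE)
  variant_tbl(
    chrom = sample(c("1", "2", "X"), n, replace = TRUE), pos = pos,
    ref = ref, alt = alt,
    qual = if (with_annots) round(stats::runif(n, 0, 100), 1) else NA_real_,
    depth = if (with_annots) sample(0:60, n, replace = TRUE) else NA_integer_
  )
}

# Independent oracle: loop-based enumeration of single-codon changes using
# only the raw codon->symbol map, no package machinery.
oracle_codon_changes <- function() {
  ct <- Biostrings::GENETIC_CODE
  rows <- list()
  for (cd in names(ct)) {
    for (p in 1:3) {
      r <- substr(cd, p, p)
      for (a in setdiff(c("A", "C", "G", "T"), r)) {
        mut <- cd
        substr(mut, p, p) <- a
        rows[[length(rows) + 1]] <- data.frame(
          codon = cd, codon_pos = p, ref = r, alt = a,
          syn = ct[[cd]] == ct[[mut]], stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

# A toy genome embedding every codon as its own one-codon CDS, once on the
# plus and once on the minus strand (the minus gene carries the reverse
# complement in genomic coordinates). Returns transcript models plus the
# gene layout needed to aim variants at specific codon positions.
codon_panel_genome <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  codons <- names(somaphyl::standard_codon_table())
  spacer <- "ATTCA"
  unit <- nchar(spacer) + 3L
  layout <- list()
  seq_parts <- character()
  offset <- 0L
  for (strand in c("+", "-")) {
    for (i in seq_along(codons)) {
      seq_parts <- c(seq_parts, spacer)
      start <- offset + nchar(spacer) + 1L
      embedded <- if (strand == "+") codons[[i]] else
        paste(rev(strsplit(chartr("ACGT", "TGCA", codons[[i]]), "")[[1]]),
              collapse = "")
      seq_parts <- c(seq_parts, embedded)
      layout[[length(layout) + 1]] <- tibble::tibble(
        codon = codons[[i]], strand = strand, start = start, end = start + 2L,
        gene = sprintf("CP%s%03d", ifelse(strand == "+", "P", "M"), i))
      offset <- offset + unit
    }
  }
  seq_parts <- c(seq_parts, spacer)
  genome_seq <- paste(seq_parts, collapse = "")
  layout <- dplyr::bind_rows(layout)
  fasta <- file.path(dir, "panel.fa")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(c(chrP = genome_seq)), fasta)
  gff <- file.path(dir, "panel.gff3")
  writeLines(c(
    "##gff-version 3",
    sprintf("chrP\ttest\tCDS\t%d\t%d\t.\t%s\t0\tID=cds-%s;Parent=tx-%s;gene_name=%s",
            layout$start, layout$end, layout$strand, layout$gene,
            layout$gene, layout$gene)
  ), gff)
  list(tm = somaphyl::transcript_models(gff, fasta), layout = layout,
       genome_seq = genome_seq, dir = dir)
}

# All 576 single-codon changes expressed as genomic variants against the
# panel genome, for one strand, joined to the enumeration table's rows.
panel_variants <- function(panel, strand) {
  cct <- somaphyl::enumerate_codon_changes()
  lay <- panel$layout[panel$layout$strand == strand, ]
  df <- dplyr::inner_join(cct, lay, by = "codon")
  if (strand == "+") {
    df$gpos <- df$start + df$codon_pos - 1L
    df$gref <- df$ref
    df$galt <- df$alt
  } else {
    df$gpos <- df$end - df$codon_pos + 1L
    df$gref <- chartr("ACGT", "TGCA", df$ref)
    df$galt <- chartr("ACGT", "TGCA", df$alt)
  }
  df
}

# Write a small cohort to disk from in-memory variant sets; returns the
# manifest path. sets = list(list(ptc=, ant=, blood=|NULL), ...)
write_mini_cohort <- function(sets, covars = NULL,
                              dir = withr::local_tempdir(.local_envir = parent.frame())) {
  rows <- lapply(seq_along(sets), function(i) {
    pid <- sprintf("P%02d", i)
    s <- sets[[i]]
    paths <- list()
    for (tis in names(s)) {
      if (is.null(s[[tis]])) next
      fn <- sprintf("%s_%s.vcf", pid, tis)
      somaphyl::write_variant_set(s[[tis]], file.path(dir, fn))
      paths[[tis]] <- fn
    }
    cv <- if (is.null(covars)) list() else as.list(covars[i, ])
    c(list(patient_id = pid, ptc_path = paths$ptc, ant_path = paths$ant,
           blood_path = paths$blood), cv)
  })
  manifest <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(list(patients = rows), manifest)
  manifest
}
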