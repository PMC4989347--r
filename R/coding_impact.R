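#' The standard genetic code
#'
#' @return Named character vector mapping all 64 codons to one-letter amino
#'   acids, with `"*"` for the three stop codons (from
#'   [Biostrings::GENETIC_CODE]): 64 codons encoding 20 amino acids plus
#'   stop.
#' @export
standard_codon_table <- function() {
  ct <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(ct), names(ct))
}

codon_change_consequence <- function(aa_ref, aa_alt) {
  dplyr::case_when(
    aa_ref == aa_alt ~ "synonymous",      # includes stop -> stop
    aa_alt == "*" ~ "stopgain",
    aa_ref == "*" ~ "stoploss",
    TRUE ~ "nonsynonymous"
  )
}

#' Exhaustively enumerate all single-nucleotide codon changes
#'
#' Every (codon, position, alternate base) triple — 64 x 3 x 3 = 576 events
#' — is tabulated with its directed substitution type, strand-collapsed
#' class and coding consequence. This is the degeneracy structure of the
#' genetic code that makes some substitution classes intrinsically more
#' likely to alter the protein than others.
#'
#' @param codon_table A codon table as from [standard_codon_table()].
#' @return A 576-row tibble with columns `codon`, `codon_pos` (1-3), `ref`,
#'   `alt`, `directed` (e.g. `"G>A"`), `class` (strand-collapsed, six
#'   levels), `aa_ref`, `aa_alt`, `consequence` (one of synonymous /
#'   nonsynonymous / stopgain / stoploss; stop-to-stop counts as
#'   synonymous).
#' @export
#' @examples
#' cct <- enumerate_codon_changes()
#' table(cct$class)  # 96 events per strand-collapsed class
enumerate_codon_changes <- function(codon_table = standard_codon_table()) {
  stopifnot(length(codon_table) == 64, !anyDuplicated(names(codon_table)))
  grid <- expand.grid(codon = names(codon_table), codon_pos = 1:3,
                      alt_i = 1:3, stringsAsFactors = FALSE)
  ref <- substr(grid$codon, grid$codon_pos, grid$codon_pos)
  alt <- mapply(function(r, i) setdiff(DNA_BASES, r)[[i]], ref, grid$alt_i,
                USE.NAMES = FALSE)
  mut <- grid$codon
  substr(mut, grid$codon_pos, grid$codon_pos) <- alt
  out <- tibble(
    codon = grid$codon, codon_pos = grid$codon_pos, ref = ref, alt = alt,
    directed = paste0(ref, ">", alt),
    class = classify_substitution(ref, alt),
    aa_ref = unname(codon_table[grid$codon]),
    aa_alt = unname(codon_table[mut])
  )
  out$consequence <- codon_change_consequence(out$aa_ref, out$aa_alt)
  out[order(out$codon, out$codon_pos, out$alt), ]
}

#' Synonymous fraction of a substitution class
#'
#' Fraction of all potential codon changes of one substitution class whose
#' encoded symbol is unchanged. With `pooled = TRUE` (default) the class is
#' strand-collapsed — e.g. `"C>T"` pools reference-C-to-T with
#' reference-G-to-A, 96 events — matching how exome-wide class fractions
#' are reported; `pooled = FALSE` restricts to the directed type (48
#' events). Stop-involving changes remain in the denominator.
#'
#' @param cct A [enumerate_codon_changes()] table.
#' @param class_label A strand-collapsed class (pooled) or directed type.
#' @param pooled Pool a class with its reverse complement?
#' @return Fraction in `[0, 1]`.
#' @export
#' @examples
#' signif(100 * synonymous_fraction(enumerate_codon_changes(), "C>T"), 3)
synonymous_fraction <- function(cct, class_label, pooled = TRUE) {
  rows <- if (pooled) cct$class == class_label else
    cct$directed == class_label
  if (!any(rows)) abort(paste0("unknown class label: ", class_label))
  mean(cct$consequence[rows] == "synonymous")
}

#' Per-class consequence fractions of the genetic code
#'
#' @param cct A [enumerate_codon_changes()] table.
#' @param pooled Strand-collapsed six classes (default) or the 12 directed
#'   types.
#' @return Tibble of `class`, `consequence`, `n`, `fraction`; fractions sum
#'   to 1 within each class.
#' @export
class_consequence_fractions <- function(cct = enumerate_codon_changes(),
                                        pooled = TRUE) {
  key <- if (pooled) cct$class else cct$directed
  tab <- as.data.frame(table(class = key, consequence = cct$consequence),
                       stringsAsFactors = FALSE)
  names(tab)[names(tab) == "Freq"] <- "n"
  tab <- as_tibble(tab)
  tab <- dplyr::group_by(tab, .data$class)
  tab <- dplyr::mutate(tab, fraction = .data$n / sum(.data$n))
  dplyr::ungroup(tab)
}

#' Load CDS transcript models from GFF3
#'
#' Reads `CDS` features from a GFF3 file into a lightweight transcript
#' model: intervals grouped by `Parent`, with per-position lookup tables and
#' spliced CDS sequences extracted from the reference, ready for
#' [call_consequence()]. Minus-strand CDS sequences are reverse-complemented
#' into transcript orientation.
#'
#' @param gff3_path Path to a GFF3 file with `CDS` features carrying
#'   `Parent=` (transcript id) and optionally `gene_name=` attributes.
#' @param genome A [Biostrings::DNAStringSet] or path to a FASTA file.
#' @return An object of class `transcript_models`.
#' @export
transcript_models <- function(gff3_path, genome) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  gff <- utils::read.table(gff3_path, sep = "\t", comment.char = "#",
                           quote = "", stringsAsFactors = FALSE,
                           col.names = c("seqid", "source", "type", "start",
                                         "end", "score", "strand", "phase",
                                         "attributes"))
  cds <- gff[gff$type == "CDS", , drop = FALSE]
  if (nrow(cds) == 0) abort("GFF3 contains no CDS features")
  attr_field <- function(x, key) {
    out <- info_field(x, key)  # GFF3 attributes share the key=value;... shape
    out
  }
  cds$transcript_id <- attr_field(cds$attributes, "Parent")
  cds$gene <- attr_field(cds$attributes, "gene_name")
  if (anyNA(cds$transcript_id)) abort("CDS feature lacks a Parent attribute")
  cds$gene[is.na(cds$gene)] <- cds$transcript_id[is.na(cds$gene)]

  chrom_seq <- stats::setNames(as.character(genome), names(genome))
  intervals <- list()
  cds_seq <- character()
  tx_meta <- list()
  for (tx in unique(cds$transcript_id)) {
    rows <- cds[cds$transcript_id == tx, , drop = FALSE]
    if (length(unique(rows$seqid)) != 1 || length(unique(rows$strand)) != 1) {
      abort(paste0("transcript ", tx, " spans chromosomes or strands"))
    }
    chrom <- rows$seqid[[1]]
    strand <- rows$strand[[1]]
    if (!chrom %in% names(chrom_seq)) {
      abort(paste0("transcript ", tx, " on unknown chromosome ", chrom))
    }
    rows <- rows[order(rows$start), , drop = FALSE]
    if (any(rows$end < rows$start) ||
        any(rows$start[-1] <= rows$end[-nrow(rows)])) {
      abort(paste0("transcript ", tx, " has invalid/overlapping CDS intervals"))
    }
    total_len <- sum(rows$end - rows$start + 1)
    if (total_len %% 3 != 0) {
      abort(paste0("CDS length of transcript ", tx,
                   " is not divisible by 3 (", total_len, ")"))
    }
    seq_fwd <- paste(substring(chrom_seq[[chrom]], rows$start, rows$end),
                     collapse = "")
    cds_seq[[tx]] <- if (strand == "+") seq_fwd else revcomp(seq_fwd)
    # offsets in transcript (5'->3') orientation
    ord <- if (strand == "+") seq_len(nrow(rows)) else rev(seq_len(nrow(rows)))
    lens <- rows$end - rows$start + 1
    off <- cumsum(c(0, lens[ord]))[seq_len(nrow(rows))]
    offsets <- integer(nrow(rows))
    offsets[ord] <- off
    intervals[[tx]] <- tibble(
      transcript_id = tx, gene = rows$gene[[1]], chrom = chrom,
      strand = strand, start = rows$start, end = rows$end,
      cds_offset = offsets
    )
    tx_meta[[tx]] <- tibble(transcript_id = tx, gene = rows$gene[[1]],
                            chrom = chrom, strand = strand,
                            cds_length = total_len)
  }
  intervals <- dplyr::bind_rows(intervals)
  # per-chromosome position -> interval-row map (0 = noncoding); first
  # transcript wins where models overlap (no multi-transcript arbitration)
  pos_map <- lapply(names(chrom_seq), function(chrom) {
    map <- integer(nchar(chrom_seq[[chrom]]))
    rows <- which(intervals$chrom == chrom)
    for (r in rev(rows)) {
      map[intervals$start[[r]]:intervals$end[[r]]] <- r
    }
    map
  })
  names(pos_map) <- names(chrom_seq)
  structure(
    list(transcripts = dplyr::bind_rows(tx_meta), intervals = intervals,
         cds_seq = cds_seq, pos_map = pos_map, chrom_seq = chrom_seq),
    class = "transcript_models"
  )
}

#' @export
print.transcript_models <- function(x, ...) {
  cat(sprintf("<transcript_models> %d transcripts on %d sequence(s)\n",
              nrow(x$transcripts), length(x$chrom_seq)))
  invisible(x)
}

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Call the coding consequence of SNSs against transcript models
#'
#' For each variant: outside any CDS the consequence is `noncoding`; inside,
#' the containing codon is mutated (after complementing the alleles into
#' transcript orientation on the minus strand) and labelled under the codon
#' table with the same rules as [enumerate_codon_changes()].
#'
#' @param variants A [variant_set()] or variant table.
#' @param tm A [transcript_models()] object.
#' @param codon_table Codon table (default: standard code).
#' @return A tibble with columns `consequence` and `gene` (`NA` gene for
#'   noncoding variants), one row per input variant, in input order.
#'   A variant whose `ref` contradicts the reference genome is a fatal
#'   error naming the locus.
#' @export
call_consequence <- function(variants, tm,
                             codon_table = standard_codon_table()) {
  v <- if (inherits(variants, "variant_set")) variants$variants else variants
  n <- nrow(v)
  consequence <- rep("noncoding", n)
  gene <- rep(NA_character_, n)
  if (n == 0) return(tibble(consequence = consequence, gene = gene))
  # reference check applies to every variant, coding or not
  for (chrom in unique(v$chrom)) {
    sel <- which(v$chrom == chrom)
    if (!chrom %in% names(tm$chrom_seq)) {
      abort(paste0("variant on unknown chromosome ", chrom))
    }
    cseq <- tm$chrom_seq[[chrom]]
    pos <- v$pos[sel]
    if (any(pos > nchar(cseq))) {
      abort(paste0("variant position beyond end of ", chrom))
    }
    genome_base <- substring(cseq, pos, pos)
    bad <- genome_base != v$ref[sel]
    if (any(bad)) {
      i <- sel[which(bad)[[1]]]
      abort(sprintf("reference mismatch at %s:%d (VCF says %s, genome has %s)",
                    v$chrom[[i]], v$pos[[i]], v$ref[[i]],
                    substring(cseq, v$pos[[i]], v$pos[[i]])))
    }
    iv <- tm$pos_map[[chrom]][pos]
    coding <- which(iv > 0)
    if (length(coding) == 0) next
    r <- iv[coding]
    idx <- sel[coding]
    strand <- tm$intervals$strand[r]
    cds_pos <- ifelse(
      strand == "+",
      tm$intervals$cds_offset[r] + v$pos[idx] - tm$intervals$start[r] + 1L,
      tm$intervals$cds_offset[r] + tm$intervals$end[r] - v$pos[idx] + 1L
    )
    codon_idx <- (cds_pos - 1L) %/% 3L + 1L
    codon_pos <- (cds_pos - 1L) %% 3L + 1L
    tx <- tm$intervals$transcript_id[r]
    codon <- substring(tm$cds_seq[tx], 3L * codon_idx - 2L, 3L * codon_idx)
    talt <- ifelse(strand == "+", v$alt[idx], complement_base(v$alt[idx]))
    mut <- codon
    substr(mut, codon_pos, codon_pos) <- talt
    consequence[idx] <- codon_change_consequence(
      unname(codon_table[codon]), unname(codon_table[mut]))
    gene[idx] <- tm$intervals$gene[r]
  }
  tibble(consequence = consequence, gene = gene)
}

#' Annotate a variant set with consequences and genes in place
#'
#' @param vs A [variant_set()].
#' @inheritParams call_consequence
#' @return The variant set with `consequence` and `gene` columns filled.
#' @export
annotate_consequences <- function(vs, tm,
                                  codon_table = standard_codon_table()) {
  calls <- call_consequence(vs, tm, codon_table)
  vs$variants$consequence <- calls$consequence
  vs$variants$gene <- calls$gene
  vs
}

NONSYN_CLASSES <- c("nonsynonymous", "stopgain", "stoploss")
CODING_CLASSES <- c("synonymous", NONSYN_CLASSES)

#' Non-synonymous fraction of coding SNSs, per subset
#'
#' For each patient and subset, the fraction of *coding* SNSs (noncoding and
#' unannotated variants excluded from the denominator) whose consequence is
#' non-synonymous in the broad sense (amino-acid change, stopgain or
#' stoploss; stopgain/stoploss also reported separately), plus a Welch t
#' contrast of each unique subset against the Common subset. Because
#' transversions alter the encoded amino acid more often than transitions, a
#' late-subset shift toward C>A transversions propagates into a higher
#' non-synonymous fraction here.
#'
#' @param partitions List of `trio_partition`s whose variants carry
#'   `consequence` annotations (see [annotate_consequences()]).
#' @return A list: `per_patient` (tibble `patient_id`, `subset`, `n_coding`,
#'   `n_nonsynonymous`, `n_stopgain`, `n_stoploss`, `fraction`), `means`
#'   (per subset, over patients with coding variants), and `tests` (named
#'   list of Welch `htest`s `unique_ptc_vs_common`, `unique_ant_vs_common`).
#' @export
nonsynonymous_fraction_by_subset <- function(partitions) {
  rows <- list()
  for (p in partitions) {
    for (s in c("common", "unique_ptc", "unique_ant")) {
      v <- p[[s]]$variants
      coding <- v$consequence %in% CODING_CLASSES
      rows[[length(rows) + 1]] <- tibble(
        patient_id = p$patient_id, subset = s,
        n_coding = sum(coding),
        n_nonsynonymous = sum(v$consequence %in% NONSYN_CLASSES),
        n_stopgain = sum(v$consequence == "stopgain"),
        n_stoploss = sum(v$consequence == "stoploss"),
        fraction = if (any(coding)) {
          sum(v$consequence[coding] %in% NONSYN_CLASSES) / sum(coding)
        } else {
          NA_real_
        }
      )
    }
  }
  per_patient <- dplyr::bind_rows(rows)
  ok <- !is.na(per_patient$fraction)
  means <- named_vec(tapply(per_patient$fraction[ok],
                            per_patient$subset[ok],
                            mean)[c("common", "unique_ptc", "unique_ant")])
  frac_of <- function(s) {
    per_patient$fraction[per_patient$subset == s &
                           !is.na(per_patient$fraction)]
  }
  tests <- list(
    unique_ptc_vs_common = safe_welch(frac_of("unique_ptc"),
                                      frac_of("common")),
    unique_ant_vs_common = safe_welch(frac_of("unique_ant"),
                                      frac_of("common"))
  )
  list(per_patient = per_patient, means = means, tests = tests)
}
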