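#' Configuration for the synthetic trio-cohort generator
#'
#' The generator emulates the evolutionary structure the analysis assumes:
#' every patient starts from a large germline pool laid down in the zygote,
#' accrues early-embryonic variants shared by all tissues, then — after the
#' hematopoietic lineage (blood) has diverged — thyroid-lineage variants
#' shared by tumor and adjacent-normal tissue, and finally tissue-exclusive
#' late pools after the malignant/non-malignant split. Early-stage variants
#' draw their substitution class from a C>T-dominant spectrum (spontaneous
#' deamination), late-stage variants from a C>A-enriched one, so the
#' spectral shift between Common and Unique subsets is built in and its
#' size is known exactly from the configuration.
#'
#' Pool-size means are scaled-down study conditions (roughly one fifth of a
#' thyroid exome's SNS load) so a 20-patient cohort simulates in seconds.
#'
#' @param n_patients Number of patients (default 20).
#' @param seed Integer seed; the same configuration yields byte-identical
#'   output files.
#' @param n_germline,n_early_shared,n_thyroid_shared,n_late_ptc,n_late_ant
#'   Poisson means of the per-patient variant pools at each evolutionary
#'   stage.
#' @param early_spectrum,late_spectrum Named probability vectors over the
#'   six strand-collapsed substitution classes (must sum to 1).
#' @param p_deleterious_given_nonsyn,p_deleterious_given_syn Per-predictor
#'   probability that one of the five upstream impact predictors calls a
#'   variant damaging, conditional on the variant being non-synonymous
#'   (incl. stopgain/stoploss) vs not.
#' @param burden_offset_braf Extra mean late-PTC variants for BRAF-mutant
#'   patients (the generator's only covariate effect).
#' @param fraction_braf Fraction of patients flagged BRAF-mutant; the count
#'   `round(fraction_braf * n_patients)` is assigned exactly, to randomly
#'   chosen patients.
#' @param fraction_blood Fraction of patients with a banked blood sample;
#'   at least 2 and exactly `round(fraction_blood * n_patients)` patients
#'   (the first ones, deterministically) get one.
#' @param fraction_known_germline Probability that a germline-stage variant
#'   appears in the emitted known-sites exclusion list (a dbSNP stand-in
#'   for filter sweeps).
#' @param depth_mean,qual_mean Means of the simulated per-variant read
#'   depth (Poisson) and quality score (normal, sd 10).
#' @param genome Toy genome layout: `n_genes` single-interval CDS genes of
#'   `cds_codons` codons each, alternating strands, separated by
#'   `intergenic_len` bp on one chromosome `chrom`.
#' @return A `sim_config` object (validated list).
#' @export
sim_config <- function(n_patients = 20,
                       seed = 1,
                       n_germline = 650,
                       n_early_shared = 150,
                       n_thyroid_shared = 150,
                       n_late_ptc = 280,
                       n_late_ant = 280,
                       early_spectrum = c("C>A" = 0.05, "C>G" = 0.05,
                                          "C>T" = 0.65, "T>A" = 0.05,
                                          "T>C" = 0.15, "T>G" = 0.05),
                       late_spectrum = c("C>A" = 0.40, "C>G" = 0.08,
                                         "C>T" = 0.25, "T>A" = 0.08,
                                         "T>C" = 0.12, "T>G" = 0.07),
                       p_deleterious_given_nonsyn = 0.35,
                       p_deleterious_given_syn = 0.05,
                       burden_offset_braf = 200,
                       fraction_braf = 0.415,
                       fraction_blood = 9 / 53,
                       fraction_known_germline = 0.3,
                       depth_mean = 60,
                       qual_mean = 60,
                       genome = list(n_genes = 40, cds_codons = 250,
                                     intergenic_len = 800, chrom = "chr1")) {
  check_spectrum <- function(s, what) {
    if (!setequal(names(s), SUBSTITUTION_CLASSES) ||
        abs(sum(s) - 1) > 1e-8 || any(s < 0)) {
      abort(paste0(what, " must be a probability vector over ",
                   toString(SUBSTITUTION_CLASSES)))
    }
  }
  check_spectrum(early_spectrum, "early_spectrum")
  check_spectrum(late_spectrum, "late_spectrum")
  means <- c(n_germline, n_early_shared, n_thyroid_shared, n_late_ptc,
             n_late_ant, burden_offset_braf)
  stopifnot(all(means >= 0), n_patients >= 1,
            p_deleterious_given_nonsyn >= 0, p_deleterious_given_nonsyn <= 1,
            p_deleterious_given_syn >= 0, p_deleterious_given_syn <= 1,
            fraction_braf >= 0, fraction_braf <= 1,
            fraction_blood >= 0, fraction_blood <= 1)
  structure(
    list(n_patients = as.integer(n_patients), seed = as.integer(seed),
         n_germline = n_germline, n_early_shared = n_early_shared,
         n_thyroid_shared = n_thyroid_shared, n_late_ptc = n_late_ptc,
         n_late_ant = n_late_ant,
         early_spectrum = early_spectrum[SUBSTITUTION_CLASSES],
         late_spectrum = late_spectrum[SUBSTITUTION_CLASSES],
         p_deleterious_given_nonsyn = p_deleterious_given_nonsyn,
         p_deleterious_given_syn = p_deleterious_given_syn,
         burden_offset_braf = burden_offset_braf,
         fraction_braf = fraction_braf, fraction_blood = fraction_blood,
         fraction_known_germline = fraction_known_germline,
         depth_mean = depth_mean, qual_mean = qual_mean, genome = genome),
    class = "sim_config"
  )
}

# Emit the toy genome (FASTA + GFF3) under the current RNG state and return
# its transcript models.
simulate_toy_genome <- function(cfg, dir) {
  g <- cfg$genome
  gene_len <- 3L * g$cds_codons
  unit <- gene_len + g$intergenic_len
  total_len <- g$n_genes * unit + g$intergenic_len
  seq <- paste(sample(DNA_BASES, total_len, replace = TRUE), collapse = "")
  fasta_path <- file.path(dir, "toy_genome.fa")
  dna <- Biostrings::DNAStringSet(stats::setNames(seq, g$chrom))
  Biostrings::writeXStringSet(dna, fasta_path, width = 80)
  starts <- g$intergenic_len + (seq_len(g$n_genes) - 1L) * unit + 1L
  gene_ids <- sprintf("GENE%03d", seq_len(g$n_genes))
  strands <- rep(c("+", "-"), length.out = g$n_genes)
  gff_path <- file.path(dir, "toy_genome.gff3")
  lines <- c(
    "##gff-version 3",
    sprintf("##sequence-region %s 1 %d", g$chrom, total_len),
    sprintf("%s\tsomaphyl_sim\tCDS\t%d\t%d\t.\t%s\t0\tID=cds-%s;Parent=%s;gene_name=%s",
            g$chrom, starts, starts + gene_len - 1L, strands,
            gene_ids, paste0("tx-", gene_ids), gene_ids)
  )
  writeLines(lines, gff_path)
  list(fasta_path = fasta_path, gff_path = gff_path,
       tm = transcript_models(gff_path, fasta_path))
}

# Draw `n` SNSs with classes from `spectrum`, placing each at an unused
# reference position whose base is compatible with the class (the purine
# position carries the reverse-complement substitution). `avail` is an
# environment holding shuffled position queues `cg` and `ta`.
draw_stage_variants <- function(n, spectrum, avail, chrom_seq, chrom) {
  if (n == 0) return(empty_variant_tbl()[, c("chrom", "pos", "ref", "alt")])
  classes <- sample(SUBSTITUTION_CLASSES, n, replace = TRUE, prob = spectrum)
  need_cg <- startsWith(classes, "C")
  n_cg <- sum(need_cg)
  n_ta <- n - n_cg
  if (n_cg > length(avail$cg) || n_ta > length(avail$ta)) {
    abort(paste0("toy genome exhausted while placing variants; ",
                 "increase genome$n_genes or cds_codons"))
  }
  pos <- integer(n)
  if (n_cg > 0) {
    pos[need_cg] <- avail$cg[seq_len(n_cg)]
    avail$cg <- avail$cg[-seq_len(n_cg)]
  }
  if (n_ta > 0) {
    pos[!need_cg] <- avail$ta[seq_len(n_ta)]
    avail$ta <- avail$ta[-seq_len(n_ta)]
  }
  ref <- substring(chrom_seq, pos, pos)
  pyr_alt <- substr(classes, 3, 3)
  alt <- ifelse(ref %in% c("C", "T"), pyr_alt, complement_base(pyr_alt))
  tibble(chrom = chrom, pos = pos, ref = ref, alt = alt)
}

#' Simulate a synthetic tumor/adjacent-normal/blood cohort
#'
#' Generates a toy genome, per-patient variant pools at five evolutionary
#' stages, and writes everything in the formats the I/O layer reads: one
#' VCF per sample (annotated with `DP`, `GENE` and `CSQ`), a YAML manifest
#' with clinical covariates, a deleteriousness predictor table, a
#' known-sites exclusion list, and a truth table recording each variant's
#' stage for parameter-recovery tests.
#'
#' Tissue membership follows the lineage model: blood carries germline +
#' early-shared variants; tumor and adjacent-normal each carry germline +
#' early-shared + thyroid-shared plus their own late pool. BRAF-mutant
#' patients receive `burden_offset_braf` extra expected late-PTC variants.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return A list: `manifest_path`, `truth` (tibble with `patient_id`,
#'   `stage`, key columns, `class`, `gene`, `consequence`, `votes`),
#'   `votes` (named vector), `paths` (named list incl. `fasta`, `gff3`,
#'   `votes`, `exclusion`, `truth`), `tm` (transcript models) and `config`.
#' @export
simulate_cohort <- function(cfg = sim_config(), dir = tempfile("somaphyl_sim")) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)
  gen <- simulate_toy_genome(cfg, dir)
  chrom <- cfg$genome$chrom
  chrom_seq <- gen$tm$chrom_seq[[chrom]]
  bases <- strsplit(chrom_seq, "")[[1]]
  pos_cg <- which(bases %in% c("C", "G"))
  pos_ta <- which(bases %in% c("T", "A"))
  contigs <- stats::setNames(nchar(chrom_seq), chrom)

  n <- cfg$n_patients
  patient_ids <- sprintf("P%02d", seq_len(n))
  n_braf <- round(cfg$fraction_braf * n)
  braf <- logical(n)
  braf[sample.int(n, n_braf)] <- TRUE
  n_blood <- min(n, max(2L, round(cfg$fraction_blood * n)))
  has_blood <- seq_len(n) <= n_blood
  age <- pmin(97, pmax(16, round(stats::rnorm(n, 49, 15))))
  sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.714, 0.286))
  race <- sample(c("Caucasian", "African-American", "Hispanic", "Other"),
                 n, replace = TRUE, prob = c(0.7, 0.1, 0.1, 0.1))
  stage <- sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                  prob = c(0.5, 0.2, 0.2, 0.1))
  histology <- sample(c("classical", "follicular-variant", "tall-cell"),
                      n, replace = TRUE, prob = c(0.7, 0.2, 0.1))

  stage_means <- function(i) c(
    germline = cfg$n_germline, early_shared = cfg$n_early_shared,
    thyroid_shared = cfg$n_thyroid_shared,
    late_ptc = cfg$n_late_ptc + if (braf[[i]]) cfg$burden_offset_braf else 0,
    late_ant = cfg$n_late_ant
  )
  early_stages <- c("germline", "early_shared", "thyroid_shared")

  truth <- list()
  manifest_rows <- list()
  for (i in seq_len(n)) {
    pid <- patient_ids[[i]]
    avail <- new.env(parent = emptyenv())
    avail$cg <- sample(pos_cg)
    avail$ta <- sample(pos_ta)
    sizes <- stats::rpois(5, stage_means(i))
    names(sizes) <- names(stage_means(i))
    pools <- lapply(names(sizes), function(st) {
      sp <- if (st %in% early_stages) cfg$early_spectrum else cfg$late_spectrum
      v <- draw_stage_variants(sizes[[st]], sp, avail, chrom_seq, chrom)
      v$stage <- rep(st, nrow(v))
      v
    })
    pv <- dplyr::bind_rows(pools)
    ann <- call_consequence(pv, gen$tm)
    pv$gene <- ann$gene
    pv$consequence <- ann$consequence
    pv$depth <- stats::rpois(nrow(pv), cfg$depth_mean)
    pv$qual <- pmax(0, round(stats::rnorm(nrow(pv), cfg$qual_mean, 10), 1))
    pv$patient_id <- pid
    truth[[i]] <- pv

    tissue_rows <- list(
      PTC = pv$stage %in% c(early_stages, "late_ptc"),
      ANT = pv$stage %in% c(early_stages, "late_ant"),
      BLOOD = pv$stage %in% c("germline", "early_shared")
    )
    paths <- list()
    for (tis in names(tissue_rows)) {
      if (tis == "BLOOD" && !has_blood[[i]]) next
      vtab <- pv[tissue_rows[[tis]],
                 c("chrom", "pos", "ref", "alt", "qual", "depth", "gene",
                   "consequence")]
      vtab$deleterious_votes <- NA_integer_
      vs <- variant_set(vtab, paste0(pid, "_", tis), tis)
      fn <- paste0(pid, "_", tolower(tis), ".vcf")
      write_variant_set(vs, file.path(dir, fn), contigs = contigs)
      paths[[tis]] <- fn
    }
    manifest_rows[[i]] <- list(
      patient_id = pid, ptc_path = paths$PTC, ant_path = paths$ANT,
      blood_path = paths$BLOOD, age = age[[i]], sex = sex[[i]],
      race = race[[i]], tnm_stage = stage[[i]], braf_mutant = braf[[i]],
      histology = histology[[i]]
    )
  }
  truth <- dplyr::bind_rows(truth)
  truth$class <- classify_substitution(truth$ref, truth$alt)

  # deleteriousness votes: one draw per unique variant key cohort-wide,
  # conditional on consequence (predictors are deterministic per variant)
  keys <- paste(truth$chrom, truth$pos, truth$ref, truth$alt, sep = ":")
  first <- !duplicated(keys)
  p_vote <- ifelse(truth$consequence[first] %in% NONSYN_CLASSES,
                   cfg$p_deleterious_given_nonsyn,
                   cfg$p_deleterious_given_syn)
  votes <- stats::setNames(stats::rbinom(sum(first), 5, p_vote), keys[first])
  truth$votes <- unname(votes[keys])
  votes_path <- file.path(dir, "deleteriousness.tsv")
  write_deleteriousness_table(votes, votes_path)

  # dbSNP-style known-sites list sampled from germline-stage variants
  germ_keys <- unique(keys[truth$stage == "germline"])
  known <- germ_keys[stats::runif(length(germ_keys)) <
                       cfg$fraction_known_germline]
  excl_path <- file.path(dir, "known_sites.tsv")
  parts <- strsplit(known, ":", fixed = TRUE)
  utils::write.table(
    data.frame(chrom = vapply(parts, `[[`, "", 1),
               pos = vapply(parts, `[[`, "", 2),
               ref = vapply(parts, `[[`, "", 3),
               alt = vapply(parts, `[[`, "", 4)),
    excl_path, sep = "\t", quote = FALSE, row.names = FALSE)

  manifest_path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(list(patients = manifest_rows), manifest_path)
  truth_path <- file.path(dir, "truth.tsv")
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(
    manifest_path = manifest_path, truth = truth, votes = votes,
    paths = list(dir = dir, fasta = gen$fasta_path, gff3 = gen$gff_path,
                 votes = votes_path, exclusion = excl_path,
                 truth = truth_path),
    tm = gen$tm, config = cfg
  )
}

#' Simulate an external blood-only comparison cohort
#'
#' Generates germline-spectrum-only variant sets standing in for an
#' external population cohort (the role 1000 Genomes blood exomes play in a
#' burden comparison): each sample carries an independent Poisson
#' (`n_germline`) draw of early-spectrum variants, annotated and with
#' predictor votes assigned under the same conditional model as
#' [simulate_cohort()].
#'
#' @param cfg A [sim_config()]; `cfg$seed` seeds the draw, so a comparison
#'   cohort built with a different seed shares no construction with the
#'   trio cohort.
#' @param n_samples Number of blood-only samples (default 10).
#' @param tm Optional [transcript_models()] to reuse (e.g. the trio
#'   cohort's toy genome); by default a genome is generated from `cfg`
#'   into `dir`.
#' @param dir Output directory for the genome when `tm` is not supplied.
#' @return A list: `sets` (list of [variant_set()]s, tissue `"BLOOD"`),
#'   `votes` (named vector covering the sets' variants).
#' @export
simulate_comparison_cohort <- function(cfg = sim_config(), n_samples = 10,
                                       tm = NULL,
                                       dir = tempfile("somaphyl_cmp")) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  if (is.null(tm)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    tm <- simulate_toy_genome(cfg, dir)$tm
  }
  chrom <- cfg$genome$chrom
  chrom_seq <- tm$chrom_seq[[chrom]]
  bases <- strsplit(chrom_seq, "")[[1]]
  pos_cg <- which(bases %in% c("C", "G"))
  pos_ta <- which(bases %in% c("T", "A"))
  sets <- list()
  all_keys <- character()
  all_p <- numeric()
  for (i in seq_len(n_samples)) {
    avail <- new.env(parent = emptyenv())
    avail$cg <- sample(pos_cg)
    avail$ta <- sample(pos_ta)
    v <- draw_stage_variants(stats::rpois(1, cfg$n_germline),
                             cfg$early_spectrum, avail, chrom_seq, chrom)
    ann <- call_consequence(v, tm)
    v$gene <- ann$gene
    v$consequence <- ann$consequence
    v$depth <- stats::rpois(nrow(v), cfg$depth_mean)
    v$qual <- pmax(0, round(stats::rnorm(nrow(v), cfg$qual_mean, 10), 1))
    v$deleterious_votes <- NA_integer_
    sid <- sprintf("CMP%02d", i)
    sets[[sid]] <- variant_set(v, sid, "BLOOD")
    keys <- variant_keys(sets[[sid]])
    new <- !(keys %in% all_keys)
    all_keys <- c(all_keys, keys[new])
    all_p <- c(all_p, ifelse(
      sets[[sid]]$variants$consequence[new] %in% NONSYN_CLASSES,
      cfg$p_deleterious_given_nonsyn, cfg$p_deleterious_given_syn))
  }
  votes <- stats::setNames(stats::rbinom(length(all_keys), 5, all_p),
                           all_keys)
  list(sets = sets, votes = votes)
}
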