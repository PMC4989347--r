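#' Gene-level recurrence matrix for a gene list
#'
#' For a supplied gene list (e.g. the MAPK pathway members), records for
#' every patient the subsets — common, unique_ptc, unique_ant — in which
#' that patient carries at least one *qualifying* SNS (non-synonymous,
#' stopgain or stoploss) in each gene. Gene assignment uses the variants'
#' `gene` annotation column, not positional overlap.
#'
#' @param partitions List of `trio_partition`s with `gene` and
#'   `consequence` annotations.
#' @param gene_list Non-empty character vector of gene symbols. Genes never
#'   hit in the cohort keep an (empty) row.
#' @return A list: `matrix` (tibble gene x patient of comma-joined subset
#'   labels, `""` when unmutated), `cells` (long tibble `gene`,
#'   `patient_id`, `subset`), `per_gene` (tibble `gene`, `n_patients`,
#'   `fraction_patients` — patients with >= 1 qualifying variant anywhere),
#'   and `per_subset_means` (mean qualifying-variant count per patient in
#'   each subset, over `gene_list` genes).
#' @export
build_recurrence <- function(partitions, gene_list) {
  if (length(gene_list) == 0) abort("gene_list must be non-empty")
  gene_list <- unique(gene_list)
  n_patients <- length(partitions)
  cells <- list()
  counts <- list()
  for (p in partitions) {
    for (s in c("common", "unique_ptc", "unique_ant")) {
      v <- p[[s]]$variants
      qual <- v$consequence %in% NONSYN_CLASSES & !is.na(v$gene) &
        v$gene %in% gene_list
      counts[[length(counts) + 1]] <- tibble(
        patient_id = p$patient_id, subset = s, n_qualifying = sum(qual))
      if (any(qual)) {
        cells[[length(cells) + 1]] <- tibble(
          gene = unique(v$gene[qual]), patient_id = p$patient_id, subset = s)
      }
    }
  }
  cells <- dplyr::bind_rows(cells)
  counts <- dplyr::bind_rows(counts)
  per_gene <- tibble(gene = gene_list)
  hit_counts <- if (nrow(cells) > 0) {
    tapply(cells$patient_id, cells$gene,
           function(x) length(unique(x)))
  } else {
    integer()
  }
  per_gene$n_patients <- as.integer(ifelse(
    per_gene$gene %in% names(hit_counts), hit_counts[per_gene$gene], 0L))
  per_gene$fraction_patients <- per_gene$n_patients / n_patients
  wide <- matrix("", nrow = length(gene_list), ncol = n_patients,
                 dimnames = list(gene_list,
                                 vapply(partitions, `[[`, "", "patient_id")))
  if (nrow(cells) > 0) {
    agg <- dplyr::summarise(
      dplyr::group_by(cells, .data$gene, .data$patient_id),
      labels = paste(sort(unique(.data$subset)), collapse = ","),
      .groups = "drop")
    wide[cbind(agg$gene, agg$patient_id)] <- agg$labels
  }
  per_subset_means <- named_vec(
    tapply(counts$n_qualifying, counts$subset,
           mean)[c("common", "unique_ptc", "unique_ant")])
  list(matrix = as_tibble(wide, rownames = "gene"), cells = cells,
       per_gene = dplyr::arrange(per_gene, dplyr::desc(.data$n_patients)),
       per_subset_means = per_subset_means)
}

#' Hypergeometric over-representation test for gene sets
#'
#' A generic pathway over-representation test: for each pathway, the
#' one-sided hypergeometric tail probability of drawing at least the
#' observed number of hit genes when `length(hits)` genes are sampled
#' without replacement from a background universe, with
#' Benjamini-Hochberg correction across pathways.
#'
#' @param hits Character vector of hit gene symbols (must lie within the
#'   background).
#' @param pathway_sets Named list of non-empty character vectors of gene
#'   symbols; members outside the background are dropped before testing.
#' @param background Character vector: the gene universe (e.g. all genes
#'   with >= 1 coding SNS in the cohort).
#' @return Tibble sorted by p-value: `pathway`, `n_pathway`, `n_hits`,
#'   `expected`, `p_value`, `q_value`.
#' @export
#' @examples
#' overrepresentation_test(c("A", "B"), list(pw = c("A", "B", "C")),
#'                         background = LETTERS[1:10])
overrepresentation_test <- function(hits, pathway_sets, background) {
  hits <- unique(hits)
  background <- unique(background)
  if (!all(hits %in% background)) {
    abort("all hits must be contained in the background universe")
  }
  if (length(pathway_sets) == 0 ||
      any(lengths(pathway_sets) == 0)) {
    abort("pathway_sets must be a non-empty list of non-empty sets")
  }
  if (is.null(names(pathway_sets))) {
    names(pathway_sets) <- paste0("pathway", seq_along(pathway_sets))
  }
  N <- length(background)
  n <- length(hits)
  rows <- lapply(names(pathway_sets), function(nm) {
    pw <- unique(pathway_sets[[nm]])
    if (length(pw) > N) {
      abort(paste0("pathway '", nm, "' is larger than the background"))
    }
    pw <- intersect(pw, background)
    k <- length(intersect(hits, pw))
    K <- length(pw)
    # P(X >= k), X ~ Hypergeometric(K, N - K, n)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble(pathway = nm, n_pathway = K, n_hits = k,
           expected = n * K / N, p_value = p)
  })
  out <- dplyr::bind_rows(rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  dplyr::arrange(out, .data$p_value)
}
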