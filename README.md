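# somaphyl

Somatic-evolution analysis of matched tumor / adjacent-normal / blood
variant sets.

## The problem

When a tumor and the histologically normal tissue it arose in are exome
sequenced from the same patient, their single-nucleotide substitution
(SNS) signatures can be read as a rudimentary phylogeny of the organ.
Intersecting the two per-sample signatures on bare variant keys
`(chrom, pos, ref, alt)` splits each patient's SNSs into three disjoint
subsets:

* **Common** = `T ∩ N` — the germline plus everything accrued before the
  malignant and non-malignant lineages diverged;
* **Unique-to-tumor** = `T \ N` and **Unique-to-normal** = `N \ T` —
  late somatic changes private to one clone.

A matched blood sample, whose lineage diverged from the tissue early in
embryogenesis, dates the subsets: old subsets overlap blood heavily,
late ones barely. On top of the partition somaphyl quantifies:

* **Mutational-spectrum shifts.** SNSs are collapsed onto the six
  pyrimidine-reference classes (C>A, C>G, C>T, T>A, T>C, T>G) and
  compared between subsets via per-patient proportions (two-sided Welch
  *t*; one-way ANOVA for ≥ 3 subsets), together with
  transition:transversion (Tr:Tv) ratios and their fold-changes.
* **Genetic-code degeneracy.** All 64 × 3 × 3 = 576 single-nucleotide
  codon changes are enumerated under the standard code; per
  strand-collapsed class (96 events) the synonymous fraction follows
  exactly — 33/96 = **34.4 %** for C>T versus 19/96 = **19.8 %** for C>A
  — so a late shift from C>T toward C>A raises the non-synonymous yield
  per mutation. A minimal CDS consequence caller applies the same rules
  to concrete genomes.
* **Burden and recurrence.** Predicted-deleterious burden per subset
  (consuming 0–5 upstream predictor votes per variant), cohort burden
  associations (e.g. BRAF status, age at a 45-year cut), gene-level
  recurrence matrices for a supplied gene list, and a hypergeometric
  over-representation test with Benjamini–Hochberg correction.
* **Synthetic cohorts.** `simulate_cohort()` generates trio cohorts with
  the assumed lineage and spectral structure (and a truth table), in the
  exact formats the I/O layer reads, so the whole pipeline is testable
  without patient data.

Inputs are per-sample VCFs, a YAML/TSV cohort manifest, optional
dbSNP-style exclusion lists (VCF or TSV), an optional predictor-votes
TSV, and a FASTA + GFF3 pair for consequence calling.

## Worked example

```r
library(somaphyl)

sim    <- simulate_cohort(sim_config(n_patients = 8, seed = 42), "ex_cohort")
cohort <- load_cohort(sim$manifest_path)
parts  <- partition_cohort(cohort, filter_config(min_depth = 8))

parts[["P01"]]
#> <trio_partition> P01: common 982 | unique_ptc 289 | unique_ant 271 (shared 77.3%)
#>   blood overlap: common 0.86, unique_ptc 0.00, unique_ant 0.00

round(blood_concordance_summary(parts)$means, 3)
#>     common unique_ptc unique_ant
#>      0.859      0.000      0.000

st <- spectrum_shift_test(parts, "C>A", c("unique_ptc", "common"))
round(st$means, 3); signif(st$p_value, 3)
#> unique_ptc     common
#>      0.390      0.048
#> [1] 1.1e-10

round(trtv_fold_change(parts)$means, 2)
#> fold_ptc fold_ant
#>     6.52     6.54

cct <- enumerate_codon_changes()
signif(100 * synonymous_fraction(cct, "C>T"), 3)  # 34.4
signif(100 * synonymous_fraction(cct, "C>A"), 3)  # 19.8
```

Reading the output: patient P01 shares 77.3 % of tumor SNSs with the
matched normal tissue; the Common subset is 86 % concordant with blood
while the late subsets are absent from it; the late (unique) subsets run
at 39 % C>A against 4.8 % in the Common subset — the simulated spectral
shift, recovered with its Welch *t* p-value; the Common subset's Tr:Tv
ratio exceeds the late subsets' ~6.5-fold; and the degeneracy enumeration
explains why such a shift matters for protein impact.

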