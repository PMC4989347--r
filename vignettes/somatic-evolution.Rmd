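---
title: "Partitioning somatic evolution from matched tumor, normal and blood SNS signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning somatic evolution from matched tumor, normal and blood SNS signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

somaphyl analyses cohorts in which each patient contributes single-nucleotide
substitution (SNS) call sets from a tumor (here labelled PTC, papillary
thyroid carcinoma), the adjacent non-tumor tissue of the same gland (ANT),
and optionally peripheral blood. The premise is a simple lineage model of
the soma: all three samples descend from the zygote, blood diverges from the
thyrocyte lineage early in embryogenesis, and the malignant and
non-malignant thyrocyte clones diverge last. Every SNS therefore falls into
a stratum of this rudimentary phylogeny, and bare set algebra on variant
keys `(chrom, pos, ref, alt)` reads the strata off the data:

* `common = PTC ∩ ANT` — germline variants plus somatic changes accrued
  before the malignant/non-malignant split;
* `unique_ptc = PTC \ ANT` and `unique_ant = ANT \ PTC` — late somatic
  changes private to one clone;
* intersecting each subset with blood dates it relative to the
  hematopoietic divergence: a subset that predates it overlaps blood
  heavily, a later one hardly at all.

No clonal deconvolution, purity modelling or tree inference is attempted —
the three-way partition *is* the phylogeny used. Matching is by bare site
key; genotypes are ignored (a record's presence is the SNS's presence in
that sample's signature).

Two derived analyses sit on top of the partition:

* **Mutational spectra.** Each SNS is collapsed onto the six
  pyrimidine-reference classes C>A, C>G, C>T, T>A, T>C, T>G (a purine
  reference is reverse-complemented; this is the only convention under
  which exome-wide "C-to-X" classes are strand-independent). The
  transition:transversion ratio and per-class proportions are compared
  between subsets. The statistical unit for all shift tests is the
  *per-patient proportion*, contrasted across subsets by a two-sided Welch
  two-sample t-test (one-way ANOVA for three or more subsets); pooled-count
  summaries are available but are never the inferential unit, because
  patients — not variants — are the independent replicates.
* **Coding impact.** The genetic code's degeneracy makes some classes
  intrinsically more disruptive than others. `enumerate_codon_changes()`
  tabulates all 64 × 3 × 3 = 576 single-nucleotide codon changes; per
  strand-collapsed class there are exactly 96 events. Under the standard
  code 33/96 = 34.4 % of potential C>T changes are synonymous against
  19/96 = 19.8 % of C>A changes, so a late-life shift from C>T toward C>A
  raises the non-synonymous (and hence potentially deleterious) yield per
  mutation even at a constant mutation rate. A minimal CDS consequence
  caller (`call_consequence()`) makes the same computation on concrete
  genomes, and is verified against the exhaustive table on every one of the
  576 changes embedded on both strands.

## Conventions and numerical choices

* **Degeneracy denominators.** The per-class synonymous fractions use
  strand-pooled counting (96 events per class), count stop→stop as
  synonymous, and keep stop-involving changes in the denominator. This is
  the unique simple convention that yields both 34.4 % and 19.8 %; the
  directed, uncollapsed fractions are also computable
  (`pooled = FALSE`) for transparency. Fractions are reported to three
  significant figures (34.375 → 34.4).
* **Filters.** Inclusion requires a minimum read depth (default 8×),
  an optional quality cut-off (default off — "standard" quality thresholds
  are caller-specific, so no number is invented), and absence from any
  supplied known-variant exclusion list (dbSNP-style). Filters are
  per-variant predicates, so the retained set is order-independent;
  removals are *attributed* in the fixed order depth → quality → exclusion
  sets. Variants lacking a depth or quality annotation pass those filters
  but are tallied, since annotation completeness varies between callers.
  `filter_sweep()` re-runs partition + spectra under several
  configurations to check that spectral conclusions are not filtering
  artefacts.
* **Overlap metric.** Inter-sample and blood overlaps use the directional
  fraction `|S_i ∩ S_j| / |S_i|` ("what share of i's SNSs recur in j"),
  matching the directional phrasing of blood concordance; Jaccard is
  available as an alternative but is not the default. Fractions of empty
  subsets are reported as missing (`NA`) and excluded from cohort means
  rather than coerced to 0, which would bias means downward.
* **Degenerate statistics.** Welch tests require variance; when both
  groups are exactly constant (common in constructed examples and edge
  cases) the test object is omitted and, where a p-value is still
  meaningful, it is reported as 1 for equal means and 0 for unequal —
  perfect separation with zero variance.
* **Predicted-deleterious calls.** Upstream protein-impact predictions are
  consumed, never computed: a variant carries 0–5 "damaging" votes, and
  the default consensus rule is ≥ 1 vote among non-synonymous variants
  (configurable 1–5; counts are non-increasing in the threshold). Variants
  missing from the votes table count as 0 votes and are reported.
* **Age dichotomy.** Cohort contrasts split age at 45 years with the
  boundary age in the younger group ("older than 45" vs the rest);
  `older_inclusive = TRUE` moves it.
* **Enrichment.** The pathway over-representation test is a one-sided
  hypergeometric tail with Benjamini–Hochberg correction across pathways.
  The default background universe is a caller choice (a sensible one is
  all genes with at least one coding SNS in the cohort); pathway members
  outside the background are dropped before testing.

## The synthetic cohort generator

No patient-level data ship with the package, so `simulate_cohort()`
generates cohorts with the lineage and spectral structure above, emitting
exactly the formats the I/O layer reads (per-sample VCFs annotated with
depth, gene and consequence; a YAML manifest with covariates; a predictor
votes table; a known-sites exclusion list; a FASTA + GFF3 toy genome) plus
a truth table of each variant's stage.

Per patient, five Poisson pools are drawn and placed at unused reference
positions compatible with their substitution class:

| stage            | present in        | spectrum | default mean |
|------------------|-------------------|----------|--------------|
| germline         | blood, PTC, ANT   | early    | 650          |
| early shared     | blood, PTC, ANT   | early    | 150          |
| thyroid shared   | PTC, ANT          | early    | 150          |
| late PTC         | PTC only          | late     | 280 (+200 if BRAF-mutant) |
| late ANT         | ANT only          | late     | 280          |

The early spectrum is C>T-dominant (weight 0.65, deamination-like) and the
late spectrum C>A-enriched (weight 0.40), so the Common-vs-unique spectral
shift is built in with a known effect size. Pool means are roughly one
fifth of a thyroid exome's SNS load, chosen once so that a 20-patient
cohort simulates in seconds while keeping per-patient class proportions
tight enough for recovery tests; with these means the expected shared
fraction of PTC SNSs is 950/1230 ≈ 0.77 for BRAF-wildtype and 950/1430 ≈
0.66 for BRAF-mutant patients, inside the 57–88 % range such cohorts show.
41.5 % of patients are flagged BRAF-mutant, and the BRAF burden offset
(+200 expected late-PTC SNSs) is the generator's only covariate effect —
age, sex, stage and histology are drawn but carry no signal, so group
contrasts on them exercise machinery, not recovery. Blood is banked for
`max(2, round(9/53 · n))` patients — a deterministic count, so small
cohorts always support the blood concordance test. Per-predictor damaging
probabilities are 0.35 given a non-synonymous consequence and 0.05
otherwise, drawn once per unique variant (predictors are deterministic
functions of a variant, so recurrences share votes).

Recovery expectations follow in closed form from the configuration: the
shared fraction estimates `μ_shared / (μ_shared + μ_late)` per patient, the
late-subset C>A proportion estimates the late spectrum weight (binomial
SD `√(p(1−p)/n_i)` per patient), blood overlap of the Common subset
estimates `(μ_germline + μ_early) / μ_shared`, and the BRAF group contrast
estimates the offset. The acceptance suite checks each at three
Monte-Carlo standard errors of the cohort mean on the default
configuration (n = 20, fixed seed).

What the generator deliberately does **not** model: sequencing error,
tumor-purity contamination (real unique-ANT subsets may contain
tumor-contaminated calls; real cohorts report purities of 40–70 % and this
package, like the analysis it implements, does not correct for them),
population sharing of germline variants across patients (each patient's
loci are drawn independently, so inter-patient overlap is near zero rather
than the ~30 % a real population shows), trinucleotide context, linkage or
clustered mutations, and multi-transcript consequence arbitration (the toy
genome's CDSs do not overlap; where user-supplied models overlap, the first
transcript wins). Passing recovery tests therefore demonstrate correctness
of the set algebra, classification and estimation machinery under the
stated model — not robustness to these real-data complications.

## Problem sizes

The shipped tests run the full pipeline on a 20-patient default simulation
(~30 000 variants, ~60 VCFs) plus smaller structural checks; the whole
suite completes in a few minutes on one core. The permutation diagnostic
for the enrichment test uses a 5 000-gene universe with 1 000 hit draws so
the hypergeometric p-value support is dense enough for a meaningful
uniformity check (with small universes the discreteness of the tail
probability, not any defect of the test, dominates a Kolmogorov–Smirnov
comparison).

## Limitations

* Variant identity is site-level; two samples sharing a site with
  different genotypes are treated as sharing the SNS.
* The consequence caller handles single-transcript, non-overlapping CDS
  models with no splice/UTR classes — it supports degeneracy accounting on
  toy genomes, not general annotation.
* Welch tests on proportions near 0/1 are used untransformed by default
  (matching the analysis family the partition supports); an arcsine-sqrt
  transform can be applied upstream by the user if desired.
* The blood concordance contrast pools the two unique subsets' fractions
  into one group, so its p-value treats two fractions per patient as
  independent observations.
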