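Package: somaphyl
Title: Somatic Evolution Analysis of Matched Tumor, Adjacent-Normal and
    Blood Variant Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for dissecting the somatic evolutionary history of a
    tissue from matched per-sample single-nucleotide substitution (SNS)
    call sets. Per-patient tumor/adjacent-normal signatures are
    partitioned at their evolutionary branch point into Common,
    Unique-to-tumor and Unique-to-normal subsets, optionally anchored by
    a blood sample that diverged earlier in development. The package
    quantifies mutational-spectrum shifts between early and late subsets
    (six strand-collapsed substitution classes, transition:transversion
    ratios), enumerates the genetic code's degeneracy per substitution
    class, summarises predicted-deleterious burden, reports gene-level
    recurrence with a hypergeometric over-representation test, and ships
    a synthetic trio-cohort simulator so the full pipeline is testable
    end to end without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
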