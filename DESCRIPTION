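Package: sgcohort
Title: Somatic Cohort Analytics for Salivary Gland Tumour Exomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Cohort-scale post-processing of tumour/normal exome calls for
    rare salivary gland tumour studies: a somatic variant refinement cascade
    (common-SNP exclusion, in-cis SNV to MNV merging, allele-length and VAF
    retention rules, target-proximity restriction, hotspot rescue), tumour
    mutation burden over a flanked coding target space with rank-sum cohort
    comparison, allele-specific copy-number analytics (altered-genome
    fraction, broad arm events, chromothripsis CN-state-switch scoring with
    chromosome-length scaling, focal-event post-filters, two-hit biallelic
    inactivation calling), a minimizer-proportion binomial test for taxon
    presence in classifier reports, and cohort summaries (binary alteration
    matrix, hotspot frequencies, margin-preserving mutual-exclusivity
    screen, two-proportion comparison). A seeded synthetic-cohort generator
    with planted ground truth makes every stage testable without access to
    controlled patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    VariantAnnotation,
    SummarizedExperiment,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
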