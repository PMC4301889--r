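Package: aeqtl
Title: Allelic-Expression QTL Mapping with Trans-Ethnic Fine-Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Phase-aware mapping of cis-acting regulatory variants from
    allelic expression ratios (aeQTL mapping) alongside conventional
    total-expression eQTL regression, for candidate-gene SNP panels typed
    in one or more cohorts. Includes pairwise linkage-disequilibrium
    statistics with two-locus EM haplotype frequency estimation,
    confidence-interval (Gabriel-style) haplotype blocks, greedy pairwise
    tag-SNP selection, Holm family-wise error control, Fisher's-method
    meta-analysis across cohorts, a variance-difference estimator of the
    cis share of expression variance, trans-ethnic fine-mapping reports,
    and a two-cohort synthetic data generator with population-specific
    haplotype pools for power studies and end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), yaml, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
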