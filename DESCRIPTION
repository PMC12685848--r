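Package: pgxcohort
Title: Cohort Pharmacogenetics: Star-Allele Diplotypes, CYP2D6 Copy Number,
    Metabolizer Phenotypes and CPIC Actionability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of cohort pharmacogenetic assay data for
    CYP2D6 and CYP2C19. Estimates CYP2D6 gene copy number from qPCR Ct
    measurements by the comparative delta-delta-Ct method with replicate
    aggregation, z-score quality banding and deletion/duplication
    classification; resolves star-allele diplotypes from unphased tag-SNP
    genotype calls combined with the copy-number call; translates diplotypes
    to metabolizer phenotypes via the CPIC activity-score system (CYP2D6) and
    allele-function rules (CYP2C19); computes cohort allele frequencies,
    Hardy-Weinberg chi-square and exact tests with Bonferroni correction, and
    heterozygote-deficit diagnostics; and maps phenotypes to CPIC antidepressant
    prescribing recommendations with cohort-level actionability summaries.
    Includes a truth-known synthetic cohort generator (Hardy-Weinberg or
    multi-deme substructured sampling, CNV carriers, genotyping error and Ct
    noise) so every pipeline stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
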