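Package: pedscreen
Title: Pedigree-Based Prioritization of Germline Variants in Cancer Families
Version: 0.1.0
Authors@R:
    person("pedscreen", "developers", email = "pedscreen@example.org",
           role = c("aut", "cre"))
Description: Filtering and ranking of candidate disease-predisposing germline
    variants in high-risk families. Starting from a pre-annotated multi-sample
    VCF and a pedigree whose sequenced members carry one of five
    carrier-probability statuses, the package applies a cascade of technical
    quality control, population-frequency rarity filtering, rare-variant
    sharing relatedness checks, Mendelian segregation filtering under a
    dominant model with phenocopy and probable-carrier tolerances, CADD and
    conservation score gating, and region-specific functional evaluation
    (deleteriousness consensus vote for missense variants; regulatory evidence
    and miRNA-target scoring for UTR and intergenic variants). A gene-drop
    pedigree simulator generates fully synthetic cohorts so that every stage
    of the cascade is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    methods,
    optparse,
    stats,
    utils,
    S4Vectors,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
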