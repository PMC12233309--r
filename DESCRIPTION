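Package: eqtlsurv
Title: Survival-Associated cis-eQTL Discovery with Cross-Cohort Replication
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for discovering cis expression quantitative
    trait loci (cis-eQTLs) whose target genes and genotypes are jointly
    associated with overall survival in tumour cohorts. Covers genotype and
    expression quality control, covariate-adjusted cis-eQTL mapping with
    adaptive permutation and beta-approximated empirical p-values, Cox
    proportional-hazards testing of eGenes and eQTLs under allelic and
    codominant inheritance models, Kaplan-Meier optimal-cutoff scanning,
    slope-direction prognostic-consistency classification, and strict or
    lenient cross-cohort replication. A synthetic twin-cohort generator with
    planted cis effects and proportional-hazards survival makes every stage
    testable without access-controlled patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    edgeR
Suggests:
    testthat (>= 3.0.0),
    survival,
    jsonlite,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
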