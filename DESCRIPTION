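Package: pgsrisk
Title: Polygenic Score Risk Evaluation via the Liability-Threshold Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Evaluation of polygenic risk scores (PGS) for 5-year disease
    risk prediction. Converts PGS discrimination (AUC) and disease
    prevalence into calibrated per-quantile and per-individual relative
    risks under the liability-threshold model; computes competing-risk
    age-specific 5-year absolute risks from population rate tables and
    combines them with PGS relative risks; scores genotype dosages against
    PGS Catalog style weight files with allele harmonization and
    within-subgroup standardization; assigns genetic-ancestry subgroups
    from principal-component coordinates; and quantifies discrimination
    (AUC with stratified-bootstrap intervals, paired DeLong comparisons)
    and calibration (expected/observed ratios, including case-cohort
    designs) across cohort strata. A synthetic-cohort generator with the
    same bivariate-normal liability structure provides a fully
    reproducible test surface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
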