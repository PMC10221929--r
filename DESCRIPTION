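Package: mrgut
Title: Two-Sample Mendelian Randomization of Gut Microbiota Exposures with
    Clinical Biomarker Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for two-sample Mendelian randomization of gut
    microbiota and metabolite exposures on immunoglobulin A nephropathy (IgAN)
    risk from GWAS summary statistics: instrument screening (locus-wide p-value
    threshold, greedy LD clumping, single-SNP F-statistic, allele-frequency and
    outcome-association exclusions, confounder blacklist), allele harmonization,
    four causal estimators (inverse-variance weighted, MR-Egger, weighted
    median, weighted mode), a sensitivity battery (Cochran's Q, Egger intercept,
    MR-PRESSO global/outlier/distortion tests, leave-one-out), per-taxonomic-level
    Bonferroni classification and reverse-direction analysis. Synthetic-data
    generators emulate the microbiota and disease GWAS inputs and a small
    clinical cohort so every stage is testable offline, and clinical biomarker
    statistics (ROC/AUC, Youden cutoff, confusion matrix, Pearson correlation,
    group comparisons) validate a candidate taxon against cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
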