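Package: anxgwas
Title: GWAS and Polygenic Risk Scoring for Anxiety Questionnaire Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end association pipeline for anxiety phenotypes
    measured on the Hospital Anxiety and Depression Scale (HADS-A, an
    integer 0-21 score with a clinical cutoff at 11). Provides variant
    quality control (PASS status, biallelic-only, Hardy-Weinberg exact
    test, minor allele frequency), population-structure principal
    components with a subsample stability check, per-variant logistic and
    linear genome-wide association scans with covariates, a polygenic risk
    score built from a per-SNP summary-statistic score with ridge
    regression and nested train/validation/test selection, and the
    epidemiological association statistics (contingency-table and adjusted
    odds ratios, genotype-defined metabolism groups, Bonferroni
    adjustment). A synthetic cohort generator with known ground truth
    (Balding-Nichols population structure, liability-model phenotypes)
    makes every stage testable without access to cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    parallel,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
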