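Package: famh2
Title: Family-Based Heritability of ECG and CMR Ventricular Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Variance-components heritability analysis for extended-family
    cohorts phenotyped by electrocardiography (ECG) and cardiovascular
    magnetic resonance (CMR). Derives ECG left-ventricular-hypertrophy
    indices (Sokolow-Lyon, Cornell, duration products, ECG left-ventricular
    mass) and CMR mass/volume indices from raw measurements; adjusts
    phenotypes by Box-Cox transformation and stepwise covariate selection;
    computes pedigree kinship and SNP genetic relationship matrices with
    standard genotype quality control and identity-by-state thresholding;
    fits maximum-likelihood and restricted-maximum-likelihood variance
    components models with likelihood-ratio tests and Wald-approximation
    standard errors; and provides the cross-modality comparison statistics
    (relative-pair correlations, Fisher z, heterogeneity tests, power
    simulation). Includes a gene-dropping synthetic family-cohort generator
    with known ground truth for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    MASS,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
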