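Package: aortaflow
Title: Heritability of Ascending-Aortic Haemodynamics from Cine Velocity Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: End-to-end pipeline for estimating the heritability of
    Reynolds-number haemodynamic metrics in the ascending aorta.
    Derives cross-sectional area, effective diameter, peak spatial-mean
    and maximum velocities, and the corresponding Reynolds numbers from
    cross-sectional phase-contrast velocity cines; adjusts traits for
    covariates by stepwise regression with standardised residuals and
    3-SD outlier exclusion; applies PLINK-style genotype quality control
    including an exact Hardy-Weinberg test and Mendelian-error detection;
    estimates pedigree-based heritability by maximum-likelihood variance
    components on the kinship matrix and SNP-based heritability by
    AI-REML on a genetic relationship matrix; and runs a mixed linear
    model association scan. A synthetic-cohort module generates family
    pedigrees, gene-dropped genotypes, covariates, heritable traits and
    pulsatile velocity-field cines with known ground truth so the whole
    pipeline is testable without access to private cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
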