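Package: aseshrink
Title: Scaling of Allele Counts and Shrinkage of Allele Substitution Effects in Genomic Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Weighted SNP-BLUP and GBLUP genomic evaluation with a continuous
    allele-count scaling parameter, for studying how scaling of centered allele
    counts changes estimated allele substitution effects (ASE). Provides a
    deterministic REML fitter for the weighted single-GRM model, ASE
    back-solving from direct genomic values, the closed-form single-locus
    shrinkage-ratio theory under uniform and U-shaped allele-frequency spectra
    (including the Euler-Mascheroni approximation of the U-shaped normalizing
    constant), per-MAF comparison statistics between fits, a scan of the
    scaling parameter by restricted log-likelihood and by weighted prediction
    error on a train/validation split, and a Hardy-Weinberg synthetic-data
    generator with a configurable MAF-dependent effect architecture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
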