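Package: finestructr
Title: Fine-Scale Population Structure from Haplotype Coancestry Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analyses of chromosome-painting coancestry
    ("chunkcount") matrices for fine-scale population structure:
    geographic cohort construction (great-circle parental filters and
    uniform grid subsampling), PCA on the coancestry matrix with a
    resampling-calibrated group dispersion statistic, a semi-supervised
    two-component Gaussian mixture model for east/west ancestry
    assignment with per-individual uncertainty, total variation distance
    (TVD) population trees with Newick export, and Hudson's pairwise
    F_ST with a block-jackknife standard error.  Includes a synthetic
    cohort generator (clustered geography, Dirichlet-multinomial
    chunkcounts, Balding-Nichols allele counts) with full ground truth
    for parameter-recovery testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    ape,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
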