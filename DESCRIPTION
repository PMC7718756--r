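Package: pellicle
Title: Computer-Vision Color Phenotyping and Quantitative Genetics of Walnut Pellicles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for quantitative scoring of walnut kernel
    (pellicle) color from tray photographs and for the downstream genetic
    analysis of the resulting phenotypes. Provides color-checker based
    RGB to CIELAB calibration with white-balance correction, segmentation of
    kernels from 100-well scoring trays, per-kernel L*, a*, b* measurement and
    ordinal DFA color grading; phenotype analysis (ANOVA, adjusted genotype
    means, trait correlations); Haley-Knott interval mapping on pseudo-testcross
    maps with genome-wide permutation thresholds and Bayes credible intervals;
    pedigree-based REML estimation of narrow-sense heritability and breeding
    values; SNP quality filtering, pairwise LD, and candidate-gene window
    queries. Includes seeded synthetic generators (rendered trays and color
    checkers, bi-parental crosses with planted QTL, pedigree-structured
    phenotypes) so the whole pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    car,
    emmeans,
    graphics,
    grDevices,
    jsonlite,
    jpeg,
    png,
    stats,
    tiff,
    utils
Suggests:
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
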