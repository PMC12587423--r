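Package: phenoroot
Title: Field-Based Prediction and Haplotype Mapping of Root and Canopy Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for predicting root-system-architecture and
    shoot-biomass traits of field-grown cereals from drone-captured
    multispectral vegetation indices, and for mapping genomic regions that
    control those traits. Provides a synthetic-data generator with known
    ground truth (SNP panels with block-structured linkage disequilibrium and
    planted QTL, field layouts with separable AR1xAR1 spatial noise,
    root-count-by-depth profiles, stage-wise biomass, plot images);
    per-pixel vegetation indices with OSAVI/Otsu soil masking; spatially
    adjusted genotype means (BLUEs) and broad-sense heritability from a
    linear mixed model with AR1xAR1 residuals; penalized-spline root-depth
    curves and area-under-curve proxy traits; partial least squares and
    random forest trait prediction with importance-guided variable
    selection; and a haplotype scan based on local genomic estimated
    breeding values (LGEBVs) from ridge-regression BLUP marker effects
    summed within linkage-disequilibrium blocks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    tools,
    jsonlite,
    yaml,
    ranger
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    mclust,
    knitr,
    rmarkdown
Config/testthat/edition: 3
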