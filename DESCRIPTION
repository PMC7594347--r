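Package: ultravar
Title: Variance Partitioning of Ultrasound Carcass Traits with Pedigree-Based REML
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Animal-model restricted maximum likelihood (REML) machinery for
    partitioning phenotypic variance in ultrasound-measured beef carcass traits
    (longissimus muscle area, subcutaneous fat depth, intramuscular fat) into
    technician, contemporary-group-within-technician, additive genetic, and
    residual components. Builds pedigree numerator relationship matrices and
    their sparse inverses (sire-dam and sire-maternal-grandsire modes), fits
    univariate animal models by derivative-free REML, fits trivariate
    laboratory-as-trait models to estimate between-laboratory genetic
    correlations, and provides the downstream statistics used to assess
    homogeneity of variance across image-interpretation laboratories:
    heritability, variance-component percentages, range/mean dispersion,
    Bartlett's test on technician-grouped residuals, genetic-correlation
    standard errors from average sire EBV accuracies, and Spearman rank
    correlations of sire EBVs. Includes a synthetic-data generator that
    reproduces the nested study design (contemporary groups within technicians
    within laboratories, paternal half-sib pedigrees with sires shared across
    laboratories) so every stage is testable without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
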