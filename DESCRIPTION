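Package: organoidkit
Title: Quantitative Image Analysis of Tumor Organoids in Engineered Hydrogels
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying 3D tumor-organoid cultures grown in
    collagen/Matrigel hydrogels: 3D morphometric descriptors (sphericity,
    convexity, circularity, geodesic elongation, lumen radius) with SVM
    phenotype classification, kappa-statistic feature selection and t-SNE
    embedding; early-organoid-seed motility statistics and protrusion
    extraction; subcellular EMT-marker localization scoring (junction to
    cytoplasm/nucleus ratios, log CDH1/VIM phenotype calls); collagen-lattice
    metrics (fiber thickness, density, pore diameter) and peri-organoid
    remodeling (doughnut compaction, anisotropy index); live/dead viability
    with four-parameter-logistic IG50 fitting; and the scalar assay formulas
    (2^-ddCt fold change, Z-score matrices, TGI, SRC/GC, Tan-delta). A
    synthetic phantom generator with analytic ground truth makes every stage
    testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    Rcpp,
    e1071,
    EBImage,
    Rtsne,
    minpack.lm,
    tiff,
    yaml,
    jsonlite,
    xml2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
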