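Package: bsaED
Title: Bulked-Segregant Mapping with the Euclidean-Distance Statistic
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping recessive loci in F2 populations by pooled
    whole-genome resequencing (BSA-Seq). Implements the per-SNP
    Euclidean-distance (ED) association statistic with squared-ED noise
    suppression, tricube local-linear (LOESS) genome smoothing, sliding-window
    aggregation, top-quantile thresholding and candidate-region calling, plus
    downstream candidate-SNP screening against gene models and differentially
    expressed genes. Includes a pooled-sequencing F2 simulator (Haldane
    meiosis, recessive phenotype model, read-depth sampling with sequencing
    error) so the whole pipeline is testable offline, Mendelian segregation
    chi-square tests and fine-mapping interval arithmetic, and leaf-physiology
    calculators (acetone-extract chlorophyll and carotenoid contents,
    saturation-pulse chlorophyll-fluorescence parameters).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
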