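Package: barseqpower
Title: Power Analysis for Pooled CRISPR Loss-of-Function Barcode-Sequencing Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Models pooled CRISPR loss-of-function (LOF) screens read out by
    barcode sequencing (Bar-seq). Provides the closed-form competition model
    linking per-guide mutagenesis rate and selection coefficient to barcode
    abundance over generations of growth, binomial read-count sampling at a
    chosen sequencing depth, a chi-square detection test on target versus
    pooled-control read counts, Monte-Carlo power estimation over mutagenesis
    and selection grids, and genome-wide gene-recovery curves for haploid and
    diploid populations. Also includes a semi-quantitative Sanger-chromatogram
    allele-frequency estimator (windowed peak areas from ABIF or plain-text
    traces) together with synthetic trace and fitness-effect generators used
    to validate it.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    ggplot2,
    pracma
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
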