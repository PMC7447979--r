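Package: meiodecon
Title: Deconvolution and Analysis of Meiotic Recombination Intermediate Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing strand-specific single-stranded-DNA ChIP signal at
    meiotic recombination hotspots. Infers protein binding (RPA, RAD51, DMC1)
    relative to double-strand-break sites by Toeplitz least-squares deconvolution
    against a SPO11-oligo break-offset distribution; decomposes RPA binding into
    DMC1 and RAD51 filament proportions; detects left/right-skewed hotspots;
    relates repair-template RPA to crossover outcome including relative lifespan
    inference for crossover- and non-crossover-destined intermediates; maps
    gene-conversion tracts from SNP-censored crossover and non-crossover records;
    and quantifies recombinase focus geometry on chromosome axes. A synthetic-data
    generator emulating the statistical structure of these assays makes the whole
    pipeline runnable and testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    stats,
    utils,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
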