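Package: mutacc
Title: Mutation Rates, Spectra and Structural Events from Mutation
    Accumulation Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of microbial mutation accumulation experiments
    (MAE) from per-line variant calls. Estimates spontaneous and
    mutagen-induced SNV, InDel and structural mutation rates per base
    per cell division with bootstrap confidence intervals, classifies
    single-base substitutions into the 96 COSMIC-style trinucleotide
    categories and tests sequence-context enrichment against genome
    composition, annotates InDels with tandem-repeat (replication
    slippage) context, detects aneuploidy and segmental copy-number
    variants from windowed read depth, assigns lightweight coding
    consequences from a GFF3 annotation, and generates complete
    synthetic MAE datasets with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
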