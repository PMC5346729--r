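Package: tauvc
Title: Tumor-Only Low Allele-Fraction Variant Calling via Local
    Background-Noise Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Variant calling for non-matched (tumor-only) targeted
    sequencing samples, aimed at low allele-fraction single-nucleotide
    variants and indels. The local sequencing background noise is
    estimated per candidate position by iterative modified Thompson Tau
    outlier rejection over a window of per-position alternative-read
    counts; candidates exceeding the noise level pass a statistical step
    and are then screened on variant allele fraction versus noise rate,
    mean base quality, base-quality dispersion and strand balance.
    Includes a limit-of-detection reporting mode (minimum detectable
    allele ratio per region or position), a single-position metrics
    query mode, a synthetic pileup simulator with known truth for
    validation, in-silico depth downsampling, a coverage-sensitivity
    benchmark harness, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
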