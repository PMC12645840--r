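Package: ecstox
Title: Downstream Analysis of Error-Corrected Sequencing Mutation Data for
    Genetic Toxicology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Import, filtering and statistical analysis of mutation data from
    error-corrected next-generation sequencing (ECS) mutagenicity studies.
    Provides variant categorization and trinucleotide-context annotation,
    germline/artifact filtering, minimum and maximum mutation frequency
    calculation with subtype spectra at 6/12/96/192-base resolution,
    binomial-family regression of mutation frequencies with contrast
    estimation, benchmark-dose derivation by bootstrap model averaging over
    continuous dose-response families, likelihood-ratio comparison and
    hierarchical clustering of mutation spectra, non-negative refitting of
    COSMIC-style single-base-substitution signatures, and a deterministic
    synthetic-data generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    data.table,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    VariantAnnotation,
    SummarizedExperiment,
    Rsamtools,
    lme4,
    pracma,
    jsonlite,
    ggplot2
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
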