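Package: cloneDecon
Title: Subclonal Deconvolution of Aggregate Aberration Frequencies
Version: 0.9.0
Authors@R:
    person("cloneDecon", "developers", email = "clonedecon@example.org",
           role = c("aut", "cre"))
Description: Deconvolves a single aggregate aberration-frequency vector
    (for example bulk variant allele fractions) into subclone genotypes,
    subclone mixing fractions and the clonal evolution tree relating them,
    under evolutionarity, parsimony, sparsity and shallowness constraints.
    Supports exact, interval-bound and normal measurement-error models,
    constrained nonnegative least-squares frequency fitting, polyallelic
    (multi-hit locus) extensions, multi-sample joint tree reconstruction,
    a brute-force enumeration oracle, and a simulation and benchmarking
    harness for noisy aggregates and genotype mixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges
Config/testthat/edition: 3
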