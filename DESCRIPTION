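Package: ildqc
Title: Batch-Effect Genotyping Error Detection via Interchromosomal
    Linkage Disequilibrium
Version: 0.1.0
Authors@R:
    person("ildqc", "Maintainers", email = "ildqc@example.org",
           role = c("aut", "cre"))
Description: Detects systematic (batch-effect) genotyping errors in
    multi-sample genotype data by exploiting interchromosomal linkage
    disequilibrium. Computes composite genotypic LD between variants on
    different chromosomes within populations, builds a permutation-based
    empirical null by redistributing chromosomes across individuals,
    profiles each individual's contribution (nAB) to the linkage signal,
    clusters individuals by error burden with Gaussian mixtures selected
    by AICc, and flags variants whose minor-allele presence is predicted
    by that burden using logistic and logistic mixed models with a
    likelihood-ratio test and Benjamini-Hochberg correction. Includes a
    validation simulator for batch-structured false-heterozygote errors
    and a two-locus Wright-Fisher simulator with epistatic selection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    lme4,
    stats,
    utils,
    methods,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
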