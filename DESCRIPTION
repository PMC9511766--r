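Package: DomestiScan
Title: Selection Scans for Domestication in Inbred Mouse Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects signatures of laboratory domestication by contrasting a
    diverse wild mouse group against a near-homozygous classical inbred panel.
    Implements windowed nucleotide diversity ratios, the Akey ANOVA Fst
    estimator, and a cross-population composite likelihood ratio (XP-CLR style)
    sweep scan; intersects top-ranked windows into positively selected genes;
    and provides the downstream expression-enrichment, candidate-SNP and
    2^-ddCt qPCR arithmetic used to follow up such scans. A seeded synthetic
    data module generates wild/inbred genotype panels with planted selective
    sweeps, plus expression, differential-expression and Ct fixtures, so the
    whole pipeline is testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ape,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
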