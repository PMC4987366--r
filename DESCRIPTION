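Package: ilqtl
Title: QTL Detection in Introgression-Line Libraries from Multi-Location Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for genomic libraries of introgression lines
    (ILs) phenotyped in multi-location randomized complete block trials.
    Provides data structures and I/O for IL genome composition (BED-like
    introgression maps), long-format phenotype tables with CIELab
    chroma/hue-angle trait derivation, two-way ANOVA variance partitioning
    and broad-sense heritability, per-location Dunnett many-to-one screening
    of ILs against the recurrent parent, a cross-location consistency
    filter, and an introgression-overlap resolution algorithm that merges or
    splits candidate effects into named QTLs. Includes a multi-environment
    trial simulator with planted QTL effects for power and false-discovery
    evaluation, and a curated QTL registry reader/reporter.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    mvtnorm,
    car,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
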