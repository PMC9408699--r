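Package: titinpsi
Title: Exon-Level Titin Splicing Analysis and Passive-Stress Decomposition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies exon-level alternative splicing of the giant
    sarcomeric protein titin from spliced RNA-seq alignments and relates it
    to muscle passive mechanics. Builds a counting-bin model of a single
    transcript (exons split at observed junction boundaries, with
    boundary-flanking "hang" segments), counts inclusion and exclusion
    junction evidence per bin, and computes percent-spliced-in (PSI)
    indices. Compares PSI between genotypes with pooled-SD effect sizes,
    two-way factorial ANOVA and Holm (sequential Bonferroni) correction;
    estimates the expressed mass of the alternatively spliced PEVK segment
    from per-exon masses and PSI (minimum, maximum and PSI-weighted
    estimators); predicts PCR amplicon ladders for splice variants; and
    decomposes skinned-fiber passive stress into titin-based and
    collagen-based components from serial trypsin/KCl/KI extraction
    experiments. Includes beta-binomial splice-count and ramp-and-hold
    mechanics simulators so the full pipeline is testable without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    rtracklayer,
    car
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
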