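Package: hmcScreen
Title: Screening for 5-Hydroxymethylated CpGs from Paired BS/oxBS Array Intensities
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detection of 5-hydroxymethylcytosine (5hmC) at single-CpG
    resolution from paired bisulfite (BS) and oxidative-bisulfite (oxBS)
    Infinium 450k array intensities. Implements the difference-of-proportions
    measure delta-beta(alpha) together with two offset-free alternatives
    (the methylated-intensity log-ratio and the relative loss of total
    intensity under oxBS), an alpha-sensitivity analysis with closed-form
    sign-change points, prevalence-based screening summaries, and a
    gold-standard-free concordance suite (simple matching and Hamann
    similarity, relative sensitivity/specificity/false discovery rate).
    A paired healthy/cancer intensity simulator with known per-probe 5mC and
    5hmC proportions supports validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
biocViews: DNAMethylation, Epigenetics, MethylationArray, Software
RoxygenNote: 7.3.3
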