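Package: strawlac
Title: Comparative Carbon-Source Transcriptomics for Cellulolytic Fungi
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing fungal transcriptomes across inducing
    carbon sources (e.g. a lignocellulosic substrate, lactose and a glucose
    reference). Classifies genes into substrate-response transcript groups
    from replicated log2 expression data, tests functional-category
    enrichment against the genome background with chi-square tests,
    clusters expression profiles hierarchically and renders 0-16 log2
    heat maps, scans promoter windows for degenerate (IUPAC)
    transcription-factor binding motifs with non-overlapping matching and
    tests observed site densities against a genome-density Poisson null
    via a two-sample Anderson-Darling statistic, and computes
    efficiency-corrected qPCR expression ratios with randomization and
    Welch tests plus protein-based biomass estimates. A synthetic-data
    generator with planted ground truth makes every stage testable
    end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    jsonlite,
    ape,
    pheatmap,
    Biostrings
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
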