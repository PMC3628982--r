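Package: irisgradient
Title: Dorsoventral Expression Gradient Analysis for Newt Iris Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for dorsal-versus-ventral iris RNA-seq during
    newt lens regeneration. Computes RPKM expression values from per-transcript
    unique read counts, estimates per-library detection cutoffs from
    structurally valid but signal-free microarray spots, classifies transcripts
    by dorsoventral and temporal fold-change rules (including a combined
    two-timepoint dorsoventral log2 fold-change ranking statistic and a
    zero-read exclusivity rule), performs Gene Ontology enrichment with
    Fisher's exact test and Benjamini-Hochberg false discovery rate control,
    and provides qPCR standard-curve quantification with Levene-gated t-tests
    and two-way ANOVA for validation experiments. Includes a seeded synthetic
    data generator emulating the four-library dorsal/ventral by 4/8 days
    post-lentectomy design, and published 50-transcript dorsal- and
    ventral-enriched reference tables as plain-text fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    car
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    Biostrings
Config/testthat/edition: 3
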