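Package: magpot
Title: Metabolic Potential Profiling of Metagenome-Assembled Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Functional profiling of metagenome-assembled genomes (MAGs)
    from methane-rich sediments such as terrestrial mud volcanoes.
    Identifies multiheme c-type cytochromes by CxxCH heme-binding motif
    scanning with Kyte-Doolittle C-terminal transmembrane prediction,
    scores completeness of the seven known CO2-fixation pathways and calls
    putative autotrophs, classifies putative metabolism from curated
    functional marker genes including the ANME "reverse methanogenesis"
    presence/absence check, computes amplicon alpha-diversity statistics
    (Chao1, Shannon, coverage) and taxonomy aggregation, performs absolute
    quantification by qPCR standard curve and radiotracer methane-oxidation
    rate arithmetic, and rolls up a genome-bin summary ledger. A seeded
    synthetic-data generator produces protein sets with planted motifs,
    annotation tables, ASV tables, qPCR runs and tracer incubations so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
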