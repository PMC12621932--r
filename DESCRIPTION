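Package: panelsmith
Title: Design and Evaluation of Targeted Amplicon Genotyping Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to design and evaluate multiplex amplicon panels for
    population genotyping of non-model organisms. Scans population genotype
    data for short high-diversity target regions flanked by conserved primer
    sites, filters candidates for repeats, copy-number artefacts, selection and
    inbreeding signals, selects genetically well-spaced marker sets over a
    genetic map, screens primer pools for dimers and off-target amplification
    by in-silico PCR, applies post-calling variant and kinship filter cascades,
    and evaluates sequenced panels (coverage balance, rarefaction,
    microhaplotypes). Includes a synthetic-data module that generates genomes,
    populations, annotated VCFs and read tables with the structure the pipeline
    assumes, so every step is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    seqinr,
    stats,
    utils,
    vcfR
Suggests:
    withr,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
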