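Package: songdelim
Title: Integrative Bioacoustic Species Delimitation for the Cicadetta
    brevipennis Song Group
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for acoustic species delimitation in small singing
    cicadas of the Cicadetta brevipennis group: seeded synthesis of
    calling songs with exact ground-truth annotations, amplitude-envelope
    segmentation of echemes and phrases, extraction of the standard song
    variables including the standardized power staircase of the long
    echeme, temperature-correcting general linear models with
    partial-residual classification of operational taxonomic units,
    correlation-matrix PCA, a rule-based diagnostic trait matrix with
    hybrid flagging, and group-mean uncorrected p-distances for
    mitochondrial COI/COII alignments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
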