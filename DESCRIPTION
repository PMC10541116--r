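Package: axoxl
Title: Cross-Link Mass Spectrometry Networks on Atomic Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of cleavable cross-linking mass spectrometry (XL/MS)
    interactomes against atomic models. Collapses residue-level cross-links
    onto eukaryotic ortholog groups, deduplicates them into unique
    amino-acid-resolution interactions, maps them onto PDB/mmCIF structures
    to classify Calpha-Calpha distance satisfaction against the DSSO linker
    constraint, disambiguates violations across conformational ensembles and
    head-to-tail oligomer lattices, and fits candidate models onto unassigned
    backbone by rigid-body (Kabsch) superposition. Includes a synthetic-data
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
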