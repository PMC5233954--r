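Package: pathrewire
Title: Altered Pathway Identification from Case/Control Co-Expression Network Rewiring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies and prioritizes altered and transcription-factor
    differentially regulated pathways from case/control gene expression
    matrices. Builds a single rewired co-expression network by testing the
    difference of Fisher-transformed Pearson correlations between conditions
    (FDR controlled), overlays a user-supplied TF-to-target regulatory network
    to flag regulatory rewired edges with differentially expressed targets,
    scores pathway gene sets by rewiring density and differential regulation,
    normalizes the combined score across scored pathways, and supports
    permutation significance, random-walk-with-restart disease-gene
    enrichment, per-gene network prioritization, and a Barabasi-Albert
    simulation benchmark of the whole procedure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
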