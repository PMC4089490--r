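Package: pyrinswitch
Title: Conformational Switch Analysis of Pyrin-Domain Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structural analysis of the open/closed conformational switch in
    pyrin domains (PYDs) of NLR innate-immunity receptors. Quantifies
    solvent-accessible surface area (Shrake-Rupley quadrature) and
    protein-protein interface burial, detects the Glu-Arg-Asp charge-relay
    element that locks the closed six-helix bundle, assigns alpha-helical
    segments from C-alpha geometry and calls the open (extended alpha5/6
    stem-helix) versus closed (six-helix bundle) state, locates the twofold
    axis of symmetric PYD dimers, and classifies pyrin-domain family members
    by sequence-level charge-relay intactness. Includes a generator of
    ground-truth-labelled synthetic helical bundles, stem-helix dimers and
    family alignments for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
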