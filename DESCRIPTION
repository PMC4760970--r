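Package: rigidmol
Title: Rigidity Analysis of Molecular Body-Bar-Hinge Frameworks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Combinatorial flexibility analysis of biomolecules. Proteins are
    modelled as body-bar-hinge mechanical frameworks built from their covalent
    and non-covalent interaction network, decomposed into rigid clusters with
    the (6,6)-pebble game on the associated multigraph, and analysed with
    derivative applications: hydrogen-bond dilution (simulated unfolding),
    in-silico alanine scanning, redundant/critical bond classification, and
    visualization-ready consistent cluster coloring. Includes reproducible
    PDB curation, coordinate-free covalent bond perception, deterministic
    synthetic fixture molecules, and exhaustive small-graph oracles for the
    sparsity matroid used by the pebble game.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
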