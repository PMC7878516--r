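Package: ccporigami
Title: Design and Biophysical Analysis of Coiled-Coil Protein Origami Cages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for the design and solution-state analysis of coiled-coil
    protein origami (CCPO) polyhedral cages. Covers double-trace enumeration on
    polyhedral graphs, topological contact order scoring of circular
    permutations, single- and multi-chain topology construction (asymmetric
    trims, pseudo-symmetric splits and protease-maskable interfaces),
    orthogonality-aware assignment of coiled-coil dimer modules to cage edges,
    full sequence assembly with linkers, tags and TEV cleavage sites,
    coarse-grained restrained rigid-body cage model building with ensemble
    generation, theoretical small-angle scattering (Debye sums, Guinier fits,
    pair-distance distributions, indirect Fourier transforms, chi fits and the
    volatility-ratio similarity metric), and thermodynamic curve fitting for
    circular dichroism melting (two- and three-state), 1:1 isothermal titration
    calorimetry and FRET ratios. Seeded synthetic-data generators provide
    realistic fixtures for every analysis path.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    seqinr,
    bio3d,
    minpack.lm,
    pracma,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
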