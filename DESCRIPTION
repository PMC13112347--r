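Package: pepmc
Title: Interface-Guided Peptide Design by Monte Carlo Mutagenesis with 2D
    Zernike Shape Descriptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes protein-protein interfaces from structures and
    multi-model PDB trajectory frames, extracts candidate inhibitory peptide
    segments from contact-occurrence statistics, and optimizes peptide
    sequences by Metropolis Monte Carlo against a composite cost combining
    2D Zernike shape complementarity of facing surface patches,
    coarse-grained Coulomb electrostatics, surface hydropathy compatibility,
    and a mutation-count penalty.  Includes a solvent-accessible surface
    point-cloud generator with outward normals, the patch-to-disk-image
    projection and 2D Zernike expansion machinery, residue-pair
    Lennard-Jones interface energetics, a two-bead-per-residue
    coarse-graining transform, multiple-sequence-alignment position
    frequencies, and deterministic synthetic fixtures so every stage is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
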