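Package: nmrsecstr
Title: Secondary and Super-Secondary Structure Annotation from Protein NMR Chemical Shifts
Version: 1.0.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies eleven classes of protein secondary and super-secondary
    structure (helix, beta-strand, coil, beta-turn types I, II, I', II' and
    VIII, beta-hairpins, and edge versus interior beta-strands) from assigned
    backbone NMR chemical shifts and an optional backbone torsion-angle table.
    Implements the classic chemical shift index (CSI) ternary digital filter
    against residue-specific random-coil references, a random-coil-index style
    backbone order-parameter (S2) estimator, a fractional accessible surface
    area (fASA) estimator, dihedral-based beta-turn typing with 30/45 degree
    tolerances, hairpin detection, and a seven-criterion edge-strand score.
    Reads NMR-STAR 2.1, NMR-STAR 3.1 and SHIFTY shift files plus TALOS-N style
    torsion tables, ships a forward-model synthetic-protein generator for
    closed-loop testing, and exposes the full pipeline as a command-line tool.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    optparse,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
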