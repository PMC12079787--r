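Package: bondbreakr
Title: Automated Bond-Breaking Conformer Sampling for Reactive Potential Training Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates nonequilibrium molecular conformers by staged elongation
    of chemical bonds. Chemically equivalent bonds are deduplicated with an
    atom-environment hash (a bond-centred relative of the Morgan fingerprint),
    each representative bond is stretched through a two-stage schedule with
    fixed-atom geometry optimization and NVT molecular dynamics against a
    pluggable energy/force calculator, and diverse MD snapshots are kept by
    greedy farthest-point (minimax) selection. Conformers are labelled with
    finite-temperature Fermi-Dirac fractional occupations and the N_FOD
    radical-character measure at several electronic temperatures, persisted
    with full provenance, and reaction energetics (reaction energy, barrier
    height, bond dissociation energy) can be evaluated with mean-absolute-error
    reporting. A bundled analytic toy force field and mock orbital-spectrum
    model make the whole workflow runnable and testable without any quantum
    chemistry backend.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ChemmineOB
SystemRequirements: Python (>= 3.8) with RDKit on the PATH as 'python'
    (used for SMILES parsing and seeded 3D embedding)
Config/testthat/edition: 3
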