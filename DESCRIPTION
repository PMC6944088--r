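Package: ciflint
Title: Validation of Small-Molecule Crystal-Structure Archives (CIF/FCF)
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A self-contained toolkit for validating small-molecule
    crystallographic archives. Reads CIF 1.1 structure files and FCF or
    SHELX-style HKLF4 reflection data (including embedded refinement
    payloads with checksums), expands Hall space-group symbols to full
    operator sets, and runs consistency checks on symmetry, the structural
    model (formula, density, occupancy algebra, rigid-bond displacement
    behaviour, intermolecular contacts), reflection statistics (merging
    R(int), completeness, weighted R factors and goodness of fit, analysis
    of variance, normal-probability statistics, Parsons-style absolute
    structure quotients, fabricated-data screening), difference electron
    density maps with solvent-accessible void detection, and coordinate- or
    intensity-based searches for missed symmetry and twinning. Findings are
    reported as a levelled alert report. A synthetic-structure generator
    produces internally consistent fixtures, including deliberately
    corrupted variants, so every check is exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
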