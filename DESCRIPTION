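Package: ensemblemimic
Title: Conformational Ensemble Analysis for Peptide Mimetic Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of protein conformational ensembles for the design of
    short peptide mimetics. Reads and writes multi-model PDB ensembles,
    performs optimal rigid-body (Kabsch) superposition and RMSd computation,
    Shrake-Rupley solvent-accessible surface area with trajectory-averaged
    lysine sidechain exposure, residue fluctuation (RMSF) analysis,
    average-linkage conformer clustering with medoid representatives, and
    cross-ensemble RMSd comparison between a protein and an N-terminal
    fragment. A mimetic-window selector finds the fragment region whose
    per-residue fluctuations best match the full-length protein, extends it
    with hydrophilic flanks, and builds cell-penetrating Tat fusion and
    scrambled control constructs. Includes seeded synthetic ensemble
    generators (Gaussian and elastic-network Langevin samplers) emulating
    molecular-dynamics trajectories with a planted flexible loop and a
    planted mimetic window, and a lysine cross-linker reactivity ranking
    combining sidechain exposure with an optional amine partial-charge
    descriptor.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
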