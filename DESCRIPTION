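Package: vacuform
Title: Gas-Phase Protein Compaction and Rehydration Recovery Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying what happens to protein structures that are
    transferred from solution into vacuum (as in electrospray ionization) and
    back again. Implements a gas-phase protonation-site assignment protocol
    driven by per-residue solvent accessibility and gas-phase basicity,
    projection-approximation collision cross-sections, Shrake-Rupley solvent
    accessible surface areas, grid-based van der Waals volumes, trajectory
    analytics (superposition RMSD, RMSF about an iterative average structure,
    residue contact maps with replica occupancy, geometric hydrogen-bond
    counts), and compaction/recovery bookkeeping over phase-labelled replica
    ensembles. Ships a synthetic homodimer and three-phase trajectory
    generator with analytically known ground truth so the whole pipeline can
    be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
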