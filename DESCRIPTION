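Package: masnmr
Title: Distance-Restraint Assignment and Structural Analytics for MAS NMR of Protein Filaments
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for turning magic-angle-spinning solid-state NMR cross peaks
    into distance restraints under sparse carbon-13 labeling schemes, with
    labeling-aware ambiguity resolution, homolog distance filtering and restraint
    bookkeeping (classification, bound conversion, per-residue counts, violation
    statistics).  Also provides coordinate-bundle analytics (Kabsch superposition,
    pairwise RMSD, hydrogen-bond geometry), helical filament construction from
    twist/rise parameters, rigid-body docking into density maps by random-orientation
    cross-correlation search, and trajectory-ensemble statistics (contact occupancy,
    RMSF, time-lagged independent component analysis, free-energy surfaces with
    minimax barrier estimation).  Synthetic-data generators with known ground truth
    make the whole pipeline testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
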