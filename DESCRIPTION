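Package: megplv
Title: Source-Space MEG Phase-Locking Networks with Permutation ANCOVA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for resting-state
    magnetoencephalography (MEG) functional connectivity in source space.
    Generates cohorts of phase-coupled cortical oscillators with known
    group-wise connectivity structure, projects them to magnetometer
    sensors through an analytic spherical-conductor forward model,
    reconstructs source activity with a linearly constrained minimum
    variance (LCMV) beamformer, estimates phase-locking-value (PLV)
    connectivity between atlas areas in an individually-defined alpha
    band, and compares diagnostic groups edge-wise with an age-adjusted
    permutation ANCOVA, Benjamini-Hochberg false discovery rate control
    and permutation-corrected Tukey pairwise contrasts. Includes
    resting-state-network averaging, beamformer-weight correlation
    diagnostics for source leakage, and score/volume correlation
    analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
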