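Package: phaseseed
Title: Phase Seeding for Ab Initio Solution of Non-Centrosymmetric Crystal Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study structure solution of non-centrosymmetric crystals
    by phase seeding: initial phases are discretized onto coarse angular grids
    (2, 3, 4 or 6 sampling points on the phase circle), a small seed of
    reflections receives true (discretized) phases, and the phase information
    is extended and refined to all reflections by iterative dual-space
    electron-density modification under the measured-amplitude constraint,
    optionally with free-lunch extrapolation of unmeasured reflections.
    Includes a minimal crystallographic core (unit cells, curated
    non-centrosymmetric space groups, symmetry-unique reflection generation,
    centric/restricted-phase classification, structure-factor calculation with
    Cromer-Mann form factors, E-value normalization), five seed-selection
    strategies, figures of merit (mean phase error, amplitude R factor), a
    synthetic-structure generator with powder-like peak-overlap degradation,
    and sweep drivers that locate the minimum seed size (Perc_lim) and the
    corresponding maximum tolerable phase error (MPE_lim).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
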