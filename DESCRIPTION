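Package: hv1kit
Title: Biophysical Analysis of Voltage-Gated Proton Channel Recordings,
    Somatic Mutations and Structural Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for the human voltage-gated proton channel
    (hHV1) and its variants. Fits whole-cell voltage-clamp current families
    (exponential activation and tail kinetics), builds conductance-voltage
    relations with Boltzmann fits and limiting-slope gating-charge
    estimates, standardizes kinetic comparisons between channel variants
    (perturbation energies, voltage dependence of time constants),
    evaluates proton selectivity against the Nernst potential with
    Goldman-Hodgkin-Katz permeability-ratio bounds, detects closed-state
    proton leak from holding-current shifts during bath pH exchanges,
    scans somatic-mutation tables for positional hotspots with a sliding
    residue window, and computes geometry statistics on structural
    ensembles (RMSD/RMSF, salt-bridge occupancy, axial shifts relative to
    the hydrophobic gasket, pore hydration profiles). A deterministic
    two-state gating simulator generates synthetic current families,
    mutation tables and toy structural ensembles so that every analysis
    stage is testable without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
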