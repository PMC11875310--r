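Package: thermoring
Title: Thermoring Analysis of Temperature-Gated Ion Channel Structures
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds grid-like residue noncovalent-interaction networks
    ("thermoring" structures) along a defined gating pathway of an ion
    channel from atomic coordinates, computes grid sizes as shortest round
    paths through a minimum-weight cycle basis, and evaluates an empirical
    thermodynamic model of heat gating: systematic thermal instability
    (Ti = S/N), per-grid melting temperature thresholds (Tm), structural
    thermosensitivity (Omega10) and activation enthalpy. Includes geometric
    detection of hydrogen bonds, salt bridges, pi-pi, cation-pi, CH-pi and
    lone-pair-pi contacts within and between subunits, synthetic fixture
    generators for end-to-end testing without structure downloads, and
    report writers for per-state and state-transition comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
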