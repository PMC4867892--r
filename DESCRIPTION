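Package: kranz
Title: Modelling C3-C4 Intermediate Photosynthesis and Online Carbon
    Isotope Discrimination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mechanistic modelling of net CO2 assimilation and photosynthetic
    13C discrimination in C3-C4 intermediate leaves with partial Kranz
    anatomy. Implements a two-compartment (mesophyll / bundle-sheath)
    assimilation model with Rubisco, PEP-carboxylase, PEP-regeneration and
    electron-transport limitations, a mesophyll-conductance-aware and
    ternary-corrected isotope discrimination model, point-by-point mesophyll
    conductance estimation for C3 leaves from coupled gas-exchange and
    tunable-diode-laser measurements, and concurrent fitting of A/Ci and
    Delta/Ci response curves to detect and quantify C4-cycle activity
    (bundle-sheath contribution and leakiness). Ships parameter presets for
    four Flaveria species, a synthetic measurement generator for method
    validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
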