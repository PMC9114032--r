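Package: avmsim
Title: Reduced-Order Haemodynamic Planning of Embolo-Sclerotherapy for
    Peripheral Arteriovenous Malformations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulator for staged embolo-sclerotherapy of a
    peripheral arteriovenous malformation (AVM). The AVM is represented as a
    lumped hydraulic network with the nidus as a Darcy porous element whose
    permeability falls as sclerosant is injected. The package calibrates the
    network's lumped resistances against digital subtraction angiography
    (DSA) derived flow rates, simulates the haemodynamics of each
    intervention stage, transports a contrast-agent bolus over the solved
    flow field to render virtual angiograms, estimates volumetric flow from
    angiographic frame series by the swept-volume method, and verifies the
    lumped Darcy closure against a two-dimensional Stokes-Brinkman grid
    solver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
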