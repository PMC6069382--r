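Package: shelfsim
Title: Shelf-Life Kinetics and Quality-Controlled Logistics for Smart
    Warehouses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates a sensor-network-driven smart warehouse for
    perishable produce. Predicts remaining shelf life with a first-order
    Arrhenius kinetic model (tomato firmness as the quality factor),
    reconstructs storage-room temperature and humidity fields on a lattice
    from sparse wall sensors by contiguous-element averaging, runs a
    threshold-driven monitoring loop, optimizes pallet placement with a
    recursive first-expired-first-out quality-controlled-logistics
    algorithm, and drives automated pallet transporters through a byte
    command codec, unit-step path planning and a drive-logic state
    machine. A seeded synthetic-environment generator replaces all
    hardware so every component is testable without sensors or robots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
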