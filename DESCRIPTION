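Package: orsched
Title: Elective Surgery Scheduling Under Emergency Capacity Reservation and
    Overlapping Appointment Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for patient admission scheduling in hospitals. Builds and
    solves a mixed-integer program that assigns elective surgical patients to
    operating rooms, surgeons, time blocks and days under ICU bed limits,
    infectious-patient cleaning and sequencing rules, deadlines, surgeon hour
    caps, and stochastic capacity reserved for emergency arrivals via normal
    chance constraints. Includes a solver-free schedule validator and cost
    evaluator, an exhaustive-enumeration exact solver for small instances, a
    greedy constructive heuristic with local search for large instances, a
    seeded synthetic instance generator, and an overlapping appointment
    scheduling (OLAS) clinic model with Lindley waiting-time recursions,
    Monte-Carlo cost estimation and appointment-template optimization.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
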