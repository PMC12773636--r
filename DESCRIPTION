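Package: fermflux
Title: Fermentation Balances, Stoichiometric Flux Models and Bioenergetics
    of Acetogenic Gut Bacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of anaerobic sugar fermentation by
    acetogens such as Blautia luti: molar fermentation balances with carbon and
    degree-of-reduction electron recoveries, log-linear growth-rate estimation
    from optical-density time courses, a declarative stoichiometric model of
    glucose fermentation with a formate-fed Wood-Ljungdahl pathway and
    chemiosmotic ATP accounting under alternative hydrogenase scenarios, enzyme
    specific-activity computation from spectrophotometric assay traces, and a
    seeded synthetic-data generator emulating replicated growth and resting-cell
    experiments so every stage is testable without raw instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
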