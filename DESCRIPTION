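Package: aerotraits
Title: Diagnosing Active Hypoxia Tolerance Traits of Marine Ectotherms
    from Biogeographic Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to estimate temperature-dependent hypoxia tolerance
    traits of marine ectotherms from species occurrence records paired
    with gridded ocean temperature and oxygen partial-pressure fields.
    Implements the Metabolic Index with an Arrhenius temperature
    dependence whose effective activation energy may vary linearly with
    temperature, diagnoses per-species active hypoxia tolerance (A_eco),
    its temperature sensitivity (E_eco) and the sensitivity slope (dEdT)
    by maximising the F1-score of the aerobic-habitability classifier in
    temperature-pO2 state space, and provides downstream diagnostics:
    aerobic habitat volumes over trait space, range-edge temperature
    sensitivities, occupied metabolic-index headroom, the temperature
    sensitivity of the active-to-resting metabolic rate ratio, and
    phylogenetic signal (Pagel's lambda on Grafen-scaled trees). A
    synthetic ocean climatology and species-occurrence generator with
    known ground-truth traits makes the full pipeline testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
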