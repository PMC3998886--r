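Package: mdsim
Title: Feedback-Regulated Compartment Model of Hematopoiesis and MDS Clonal Competition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates clonal competition between normal hematopoiesis and a
    myelodysplastic (MDS) clone using a nonlinear ordinary-differential-equation
    model of the stem-cell hierarchy. Six normal and five malignant maturation
    stages are coupled through two feedback signals: a proliferation signal
    driven by mature peripheral-blood cell counts and a self-renewal signal
    driven by primitive-cell occupancy of the bone-marrow niche. Provides
    analytic steady states, a takeover criterion, long-horizon scenario
    simulation with event detection, bone-marrow observables (composition,
    apoptotic and primitive-cell fractions), outcome-classification parameter
    sweeps, shipped parameter presets, and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    tibble,
    tidyr,
    yaml
Suggests:
    Matrix,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
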