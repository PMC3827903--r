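Package: osteotrace
Title: Simulation and Histomorphometry of Osteoclastic Resorption Traces
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Agent-based simulation of osteoclastic resorption pits and
    trails on digital mineralized surfaces (bone and dentin height maps),
    together with the histomorphometric quantification pipeline used to
    measure them: connected-component event detection, per-event area,
    length, width and depth morphometrics, surface roughness metrics
    (Ra/Rq), donor-level cohort summaries, and comparative statistics
    (fold changes, size histograms, depth-area plateau estimation, Welch
    t-tests). Trails are generated mechanistically by cyclic
    layer-by-layer vertical resorption combined with horizontal stepping
    of the cell front; pits by stationary elliptical excavation. Includes
    a synthetic-data stage that calibrates per-event geometry
    distributions to printed summary moments and emulates multi-donor
    cohorts for round-trip parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    tibble,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    stats,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
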