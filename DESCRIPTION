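Package: epizyme
Title: Cryptic Epistasis Analysis for Enzyme Mutant Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for detecting cryptic epistasis from orthologue
    swap mutant panels of an enzyme. Fits Michaelis-Menten kinetics and the
    kcat/Km performance statistic, decomposes the distribution of mutational
    effects (wild-type error model, half-Gaussian reflection estimate of the
    neutral class, Welch tests under false-discovery-rate control), computes
    additive and multiplicative (transition-state free-energy) independence
    null predictions for an orthologue's performance, classifies compensatory
    double mutants, estimates pairwise deleterious-interaction probabilities
    and the Dobzhansky-Muller style snowball curve, maps performance to
    fitness through a dominance hyperbola, and simulates two-lineage covarion
    and nearly-neutral evolution with residue swap experiments. Includes a
    synthetic mutant-panel generator for calibration and power studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
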