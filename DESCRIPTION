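Package: mphenosim
Title: Hybrid Cellular-Automaton Simulation of Tumor Metabolism, Immune
    Predation, and Metaphenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A seeded, configurable hybrid cellular-automaton / reaction-diffusion
    simulator of two-dimensional tumor growth under metabolic selection and
    T-cell predation. Oxygen, glucose, and protons diffuse from a dynamic
    vascular point process and are consumed or produced by tumor and normal
    cells; heritable glycolytic, acid-resistance, and PD-L1 phenotypes evolve
    by drift and selection; cytotoxic T-cells are recruited in proportion to
    tumor burden and are subject to checkpoint inhibition, acid inactivation,
    and glucose deprivation. Each tumor cell is scored on seven graded
    collective "metaphenotype" expressions (Immune Desert, PD-L1 Attack, Mooch
    PD-L1, Self-Acidify, Mooch Acid, Proliferate Fast, Starve Glucose), and an
    experiment harness runs vascular sweeps, immune-response sweeps, and
    anti-PD-L1 / pH-buffer treatment factorials with paired seeds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
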