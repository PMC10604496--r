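Package: picaco
Title: PIC-Seeded Ant Colony Optimization for Microsatellite Marker Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects reduced microsatellite marker panels that preserve the
    average Nei genetic distance of the full panel within a stated accuracy-loss
    margin. Implements an ant colony optimization (ACO) search over binary
    marker-inclusion vectors whose pheromone trails can be seeded from per-locus
    polymorphic information content (PIC), alongside PIC-rank and random
    baseline schemes, per-locus diversity statistics (Na, Nea, AR, PIC, Ho, He),
    GenAlEx-style genotype input/output, panel evaluation with Tukey and t-test
    reports, and a Balding-Nichols genotype simulator for fully reproducible
    in-silico experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
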