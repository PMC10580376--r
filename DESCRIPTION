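Package: pubsim
Title: Simulation of Immune Receptor Repertoires with Realistic Public Sequence Sharing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates synthetic adaptive immune receptor repertoire (AIRR)
    cohorts in which both background public sequences and implanted
    immune-state signal sequences follow empirically calibrated relations
    between V(D)J generation probability and population incidence. Provides
    the four-stage workflow (witness-rate feasibility assessment, baseline
    repertoire generation, public-component correction, signal implantation),
    tools to calibrate incidence models from labeled cohorts, reference-pool
    construction with k-mer pattern queries for signal selection, and
    bias-audit statistics (binomial outlier scores and likelihood ratios)
    that quantify the generation-probability discordance shortcut available
    to machine-learning methods on naively simulated benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stringr,
    ggplot2,
    jsonlite,
    yaml,
    generics,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
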