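Package: polydeg
Title: Physics-Constrained Reinforcement Learning for Degradable Polymer Generation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Generates candidate degradable polymers with a masked soft
    actor-critic agent operating on a dual sequence/graph polymer
    representation. Polymers are written in a BigSMILES-style notation
    extended with chain-initiation, termination, stochastic-point and
    cross-link tokens, and encoded both as token sequences and as
    atom/bond graphs with polymer-specific edge flags. Physics
    constraints (group-contribution formation energy, synthetic
    accessibility, cross-link density) are enforced through augmented
    Lagrangian dual updates, and a hierarchical multi-objective reward
    combines validity, enzymatic and hydrolytic degradability terms,
    diversity bonuses and pluggable property scorers. Includes seeded
    toy monomer libraries, enzyme panels and pretraining corpora so the
    full pipeline runs at desk scale, plus generation-quality metrics
    (validity, Tanimoto diversity, novelty, hypervolume).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
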