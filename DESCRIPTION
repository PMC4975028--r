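Package: fgmcohorts
Title: Mutation Cohort Dynamics Under Fisher's Geometric Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Forward-time Wright-Fisher simulation of asexual populations
    adapting on Fisher's geometric fitness landscape with full or partial
    mutational pleiotropy. Every de novo mutation is tracked from origin to
    fixation or loss, so that cohorts of mutations reaching fixation
    simultaneously under clonal interference can be detected and quantified.
    Provides a genotype-class simulation engine, a naive individual-based
    reference engine, per-lineage frequency trajectories, fixation-event logs,
    replicate-level summaries (mean-fitness dynamics, first-fixation cohort
    size distributions, cohort sizes along the adaptive walk), Gaussian
    observation-noise post-processing for comparison with evolve-and-resequence
    data, and deterministic tab-separated serialization of all result tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    tools,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
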