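Package: fluxdraft
Title: Drafting and Constraint-Based Flux Analysis of Microbial Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Draft stoichiometric metabolic models from KGML pathway files
    cross-referenced with KEGG-LIGAND-style reaction tables, reconstruct them
    with exchange, biomass, maintenance, heterologous and gap-filling edits,
    knockouts and reaction modifications, and analyse them by constraint-based
    methods: flux balance analysis (FBA) with arbitrary linear objectives,
    growth-associated-maintenance fitting, production envelopes, and dynamic
    FBA by the static optimization approach. Models are exchanged as SBML
    (Level 3 with flux-balance constraints on write; legacy Level 2 bound
    encodings on read) and networks can be rendered to SVG. A synthetic
    KEGG-like fixture generator with recorded ground truth supports fully
    offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
Suggests:
    boot,
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
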