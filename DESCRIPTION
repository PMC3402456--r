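Package: drugmoa
Title: Mechanism-of-Action Reasoning for Drug Repurposing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A typed knowledge base of drug-target, protein-protein,
    gene-disease and gene-bioprocess facts in an answer-set-programming
    fact dialect, and a stepped forward-chaining inference engine that
    derives drug-treats-disease hypotheses from seven mechanism-of-action
    rules over signed, directed molecular interactions.  Chains of
    inference steps are classified as direct or indirect, contradictory
    mechanisms (the same drug also promoting the disease) are detected
    and can block a hypothesis, and knowledge-source ablation quantifies
    the contribution of each provenance source to recall against labeled
    drug sets.  A seeded synthetic knowledge-base generator with planted
    ground-truth chains and an independent exhaustive path-enumeration
    oracle support property-based validation of the engine.
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
    purrr,
    rlang,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
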