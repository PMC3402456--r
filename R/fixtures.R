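#' Built-in worked-example knowledge bases
#'
#' Three miniature knowledge bases built in code, each holding exactly
#' the facts of a classic mechanism-of-action scenario:
#'
#' * `"dipyridamole"` — the direct-inference example: the antagonist
#'   edge to adenosine deaminase (ADA) plus the text-mined association
#'   of overexpressed ADA with cancer.
#' * `"tazarotene"` — the indirect-inference example: the agonist edge
#'   to RARA, the RARA-inhibits-EGFR interaction, and the oncogene
#'   assertion for EGFR.
#' * `"cladribine"` — the contradiction example: the agonist edge to
#'   PNP plus PNP's membership in positive regulation of cell
#'   proliferation, a cancer-promoting bioprocess.
#' * `"scenarios"` — the dipyridamole and tazarotene fact sets merged.
#'
#' @param name One of `"dipyridamole"`, `"tazarotene"`, `"cladribine"`,
#'   `"scenarios"`.
#' @return A `moa_kb` object.
#' @examples
#' infer(example_kb("dipyridamole"), "dipyridamole")
#' @export
example_kb <- function(name = c("dipyridamole", "tazarotene", "cladribine",
                                "scenarios")) {
  name <- match.arg(name)
  dipy <- list(
    interactions = tibble(subject = "dipyridamole", verb = "inhibits",
                          object = "ada", source = "drugbank",
                          evidence = "DrugBank"),
    disease_relations = tibble(protein = "ada",
                               expression_state = "overexpressed",
                               disease = "cancer", source = "text_mining",
                               evidence = "PMID: 6981287"),
    drugs = "dipyridamole", proteins = "ada", diseases = "cancer"
  )
  taza <- list(
    interactions = tibble(
      subject = c("tazarotene", "rara"), verb = c("induces", "inhibits"),
      object = c("rara", "egfr"), source = c("drugbank", "text_mining"),
      evidence = c("DrugBank", "PMID: 11788593")
    ),
    oncogenes = "egfr",
    drugs = "tazarotene", proteins = c("rara", "egfr")
  )
  args <- switch(
    name,
    dipyridamole = dipy,
    tazarotene = taza,
    cladribine = list(
      interactions = tibble(subject = "cladribine", verb = "induces",
                            object = "pnp", source = "drugbank",
                            evidence = "DrugBank"),
      bioprocess_relations = tibble(protein = "pnp",
                                    bioprocess = "pos_reg_cell_proliferation",
                                    source = "go"),
      promoting_bps = "pos_reg_cell_proliferation",
      drugs = "cladribine", proteins = "pnp"
    ),
    scenarios = list(
      interactions = bind_rows(dipy$interactions, taza$interactions),
      disease_relations = dipy$disease_relations,
      oncogenes = taza$oncogenes,
      drugs = c(dipy$drugs, taza$drugs),
      proteins = c(dipy$proteins, taza$proteins),
      diseases = dipy$diseases
    )
  )
  do.call(knowledge_base, args)
}
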