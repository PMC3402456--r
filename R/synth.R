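#' Parameters for the synthetic knowledge-base generator
#'
#' The defaults emulate the shape of a DrugBank-plus-text-mining
#' knowledge base at roughly 1/50 scale: ~19 drugs averaging ~1.8
#' drug-target edges each (matching 1704 interactions over 943 drugs),
#' a sparse signed protein-protein network with mean out-degree ~4,
#' small oncogene/suppressor fractions, and a minority of proteins
#' carrying gene-disease or gene-bioprocess relations.  See the methods
#' vignette for the sizing rationale.
#'
#' @param n_drugs,n_proteins,n_bioprocesses Entity counts.
#' @param p_drug_edge Probability a (drug, protein) pair gets a
#'   drug-target fact.
#' @param p_ppi Probability an ordered (protein, protein) pair gets a
#'   signed interaction.
#' @param frac_oncogene,frac_suppressor Per-protein probabilities of the
#'   class assertions (independent; overlap is allowed, as in curated
#'   sources).
#' @param frac_disease_rel Per-protein probability of a gene-disease
#'   relation.
#' @param frac_bp_rel Per-protein probability of a gene-bioprocess
#'   relation.
#' @param sign_split Probability an edge is `induces` (vs `inhibits`).
#' @param n_planted_chains Number of guaranteed treats chains to plant.
#' @param planted_depth Triggers per planted chain (>= 2; depth 2 plants
#'   a direct chain).
#' @param seed Integer seed; equal seeds give byte-identical serialized
#'   knowledge bases.
#' @return A validated `moa_synth_params` list.
#' @export
synth_params <- function(n_drugs = 19L, n_proteins = 80L,
                         n_bioprocesses = 8L,
                         p_drug_edge = 0.023, p_ppi = 0.05,
                         frac_oncogene = 0.04, frac_suppressor = 0.04,
                         frac_disease_rel = 0.15, frac_bp_rel = 0.2,
                         sign_split = 0.5,
                         n_planted_chains = 2L, planted_depth = 3L,
                         seed = 1L) {
  p <- list(
    n_drugs = as.integer(n_drugs), n_proteins = as.integer(n_proteins),
    n_bioprocesses = as.integer(n_bioprocesses),
    p_drug_edge = p_drug_edge, p_ppi = p_ppi,
    frac_oncogene = frac_oncogene, frac_suppressor = frac_suppressor,
    frac_disease_rel = frac_disease_rel, frac_bp_rel = frac_bp_rel,
    sign_split = sign_split,
    n_planted_chains = as.integer(n_planted_chains),
    planted_depth = as.integer(planted_depth),
    seed = as.integer(seed)
  )
  probs <- unlist(p[c("p_drug_edge", "p_ppi", "frac_oncogene",
                      "frac_suppressor", "frac_disease_rel", "frac_bp_rel",
                      "sign_split")])
  if (any(probs < 0 | probs > 1)) abort("all probabilities must be in [0, 1]")
  if (any(unlist(p[c("n_drugs", "n_proteins", "n_bioprocesses",
                     "n_planted_chains")]) < 0)) {
    abort("counts must be >= 0")
  }
  if (p$planted_depth < 2L) abort("planted_depth must be >= 2")
  if (p$n_planted_chains > 0) {
    if (p$n_planted_chains > p$n_drugs) {
      abort("infeasible: more planted chains than drugs")
    }
    if (p$n_planted_chains * (p$planted_depth - 1L) > p$n_proteins) {
      abort("infeasible: planted chains need more distinct proteins than exist")
    }
  }
  structure(p, class = "moa_synth_params")
}

#' Generate a synthetic knowledge base with planted ground truth
#'
#' Draws a random knowledge base under [synth_params()] and plants
#' `n_planted_chains` treats chains whose support facts are inserted so
#' that the engine is guaranteed to derive them (under the default
#' propagation flags with `contradiction_mode = "ignore"`; under
#' `"block"` a planted chain can be suppressed only by a promotes chain
#' of the same drug, which random facts may create).  Planted paths use
#' distinct drugs and pairwise-distinct proteins; the sign sequence is
#' random subject to derivability (after an inactivating step only
#' `induces` edges keep the signal alive under default policy).
#'
#' @param params A [synth_params()] object.
#' @return A list: `kb` (a `moa_kb`) and `planted` (trigger-level
#'   tibble of the planted chains, same layout as `infer()$chains`).
#' @examples
#' g <- generate_kb(synth_params(n_drugs = 4, n_proteins = 12, seed = 7))
#' g$kb
#' chain_keys(g$planted)
#' @export
generate_kb <- function(params = synth_params()) {
  stopifnot(inherits(params, "moa_synth_params"))
  set.seed(params$seed)

  drugs <- sprintf("drug%03d", seq_len(params$n_drugs))
  proteins <- sprintf("prot%03d", seq_len(params$n_proteins))
  bps <- sprintf("bioprocess%02d", seq_len(params$n_bioprocesses))
  diseases <- c(sprintf("cancer_type_%02d", 1:4),
                sprintf("noncancer_disease_%02d", 1:3))

  pick_verb <- function(n) {
    c("inhibits", "induces")[1L + (stats::runif(n) < params$sign_split)]
  }

  onc <- proteins[stats::runif(params$n_proteins) < params$frac_oncogene]
  sup <- proteins[stats::runif(params$n_proteins) < params$frac_suppressor]
  r <- stats::runif(params$n_bioprocesses)
  pro_bp <- bps[r < 0.4]
  res_bp <- bps[r >= 0.4 & r < 0.8]

  dt_pairs <- expand.grid(subject = drugs, object = proteins,
                          stringsAsFactors = FALSE)
  dt_pairs <- dt_pairs[stats::runif(nrow(dt_pairs)) < params$p_drug_edge, ]
  ppi_pairs <- expand.grid(subject = proteins, object = proteins,
                           stringsAsFactors = FALSE)
  ppi_pairs <- ppi_pairs[ppi_pairs$subject != ppi_pairs$object, ]
  ppi_pairs <- ppi_pairs[stats::runif(nrow(ppi_pairs)) < params$p_ppi, ]
  interactions <- tibble(
    subject = c(dt_pairs$subject, ppi_pairs$subject),
    verb = pick_verb(nrow(dt_pairs) + nrow(ppi_pairs)),
    object = c(dt_pairs$object, ppi_pairs$object),
    source = rep(c("drugbank", "text_mining"),
                 c(nrow(dt_pairs), nrow(ppi_pairs)))
  )

  has_drel <- stats::runif(params$n_proteins) < params$frac_disease_rel
  disease_relations <- tibble(
    protein = proteins[has_drel],
    expression_state = sample(c("overexpressed", "underexpressed"),
                              sum(has_drel), replace = TRUE),
    disease = sample(diseases, sum(has_drel), replace = TRUE),
    source = "text_mining"
  )
  has_bprel <- stats::runif(params$n_proteins) < params$frac_bp_rel
  bioprocess_relations <- if (params$n_bioprocesses > 0) {
    tibble(
      protein = proteins[has_bprel],
      bioprocess = sample(bps, sum(has_bprel), replace = TRUE),
      source = "go"
    )
  } else {
    tibble(protein = character(), bioprocess = character(),
           source = character())
  }

  # --- plant ground-truth chains ----------------------------------------
  planted <- list()
  if (params$n_planted_chains > 0) {
    plant_drugs <- sample(drugs, params$n_planted_chains)
    plant_prots <- sample(proteins,
                          params$n_planted_chains * (params$planted_depth - 1L))
    policy0 <- engine_policy(contradiction_mode = "ignore")
    for (k in seq_len(params$n_planted_chains)) {
      d <- plant_drugs[[k]]
      path <- plant_prots[((k - 1L) * (params$planted_depth - 1L) + 1L):
                            (k * (params$planted_depth - 1L))]
      verbs <- character(length(path))
      actions <- character(length(path))
      verbs[1] <- pick_verb(1)
      actions[1] <- if (verbs[1] == "inhibits") "inactivates" else "activates"
      if (length(path) > 1) {
        for (j in 2:length(path)) {
          verbs[j] <- if (actions[j - 1] == "inactivates") {
            "induces"                      # only live transition (R2c)
          } else {
            pick_verb(1)
          }
          actions[j] <- next_action_rule(actions[j - 1], verbs[j], policy0)$action
        }
      }
      subj <- c(d, path[-length(path)])
      interactions <- bind_rows(interactions, tibble(
        subject = subj, verb = verbs, object = path,
        source = c("drugbank", rep("text_mining", length(path) - 1L))
      ))
      triggers <- list(new_trigger(
        d, actions[1], path[1], 1L, if (verbs[1] == "inhibits") "R1a" else "R1b",
        interaction_string(d, verbs[1], path[1])
      ))
      if (length(path) > 1) {
        for (j in 2:length(path)) {
          nx <- next_action_rule(actions[j - 1], verbs[j], policy0)
          triggers[[j]] <- new_trigger(
            d, nx$action, path[j], j, nx$rule,
            interaction_string(path[j - 1], verbs[j], path[j])
          )
        }
      }
      last_a <- actions[length(path)]
      last_p <- path[length(path)]
      kind <- sample(c("disease", "gene_class", "bioprocess"), 1)
      term <- switch(
        kind,
        disease = {
          state <- if (last_a == "inactivates") "overexpressed" else "underexpressed"
          dise <- sample(diseases[1:4], 1)
          disease_relations <- bind_rows(disease_relations, tibble(
            protein = last_p, expression_state = state, disease = dise,
            source = "text_mining"
          ))
          new_trigger(d, "treats", "cancer", length(path) + 1L,
                      if (last_a == "inactivates") "R3a" else "R3b",
                      disease_relation_string(last_p, state, dise))
        },
        gene_class = {
          if (last_a == "inactivates") {
            onc <- union(onc, last_p)
            new_trigger(d, "treats", "cancer", length(path) + 1L, "R4",
                        unary_fact_string("oncogene", last_p))
          } else {
            sup <- union(sup, last_p)
            new_trigger(d, "treats", "cancer", length(path) + 1L, "R5",
                        unary_fact_string("suppressor", last_p))
          }
        },
        bioprocess = {
          bp <- sprintf("planted_bp_%02d", k)
          bps <- union(bps, bp)
          if (last_a == "inactivates") pro_bp <- union(pro_bp, bp)
          else res_bp <- union(res_bp, bp)
          bioprocess_relations <- bind_rows(bioprocess_relations, tibble(
            protein = last_p, bioprocess = bp, source = "go"
          ))
          cls_pred <- if (last_a == "inactivates") {
            "cancer_promoting_bioprocess"
          } else "cancer_resisting_bioprocess"
          new_trigger(d, "treats", "cancer", length(path) + 1L,
                      if (last_a == "inactivates") "R6" else "R7",
                      c(bioprocess_relation_string(last_p, bp),
                        unary_fact_string(cls_pred, bp)))
        }
      )
      planted[[k]] <- c(triggers, list(term))
    }
  }

  kb <- knowledge_base(
    interactions = interactions,
    disease_relations = disease_relations,
    bioprocess_relations = bioprocess_relations,
    drugs = drugs, proteins = proteins, diseases = diseases,
    bioprocesses = bps,
    oncogenes = onc, suppressors = sup,
    promoting_bps = pro_bp, resisting_bps = res_bp,
    auto_register = FALSE
  )
  list(kb = kb, planted = chains_to_tibble(planted))
}
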