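#' Exhaustive path-enumeration oracle
#'
#' An independent correctness reference for [infer()].  Instead of
#' stepped forward chaining, it first enumerates every simple directed
#' path that starts at the drug and follows interaction edges (up to
#' `policy$max_depth` edges, never revisiting a protein), then replays
#' the rule definitions along each path with straight-line code that
#' shares no traversal logic with the engine.  Only the final chain
#' canonicalization (ordering and deduplication) is shared, so that the
#' two chain sets are directly comparable.
#'
#' Intended for small knowledge bases only; refuses to run above 50
#' registered proteins.
#'
#' @inheritParams infer
#' @return A list with the same chain containers as a `moa_inference`:
#'   `chains`, `chain_info` (post-policy treats chains), `promoting`,
#'   `promoting_info`, `verdict`.
#' @export
oracle_infer <- function(kb, drug, disease_class = "cancer",
                         map = disease_class_map(disease_class),
                         policy = engine_policy()) {
  if (length(kb_proteins(kb)) > 50) {
    abort("oracle_infer is an exhaustive reference; refusing above 50 proteins")
  }
  if (!drug %in% kb_drugs(kb)) {
    abort(sprintf("drug '%s' is not registered in the knowledge base", drug))
  }

  inter <- kb$interactions
  drel <- kb$disease_relations
  bprel <- kb$bioprocess_relations
  onc <- kb$classes$id[kb$classes$class == "oncogene"]
  sup <- kb$classes$id[kb$classes$class == "suppressor"]
  pro_bp <- kb$classes$id[kb$classes$class == "promoting_bp"]
  res_bp <- kb$classes$id[kb$classes$class == "resisting_bp"]
  in_class <- function(d) {
    cls <- map_disease_class(d, map)
    !is.na(cls) & cls == disease_class
  }

  # 1. all simple paths of 1..max_depth edges starting at the drug
  paths <- list()
  grow <- function(node, edge_idx, seen) {
    nxt <- which(inter$subject == node)
    for (i in nxt) {
      obj <- inter$object[[i]]
      if (obj %in% seen) next
      here <- c(edge_idx, i)
      paths[[length(paths) + 1L]] <<- here
      if (length(here) < policy$max_depth) grow(obj, here, c(seen, obj))
    }
  }
  grow(drug, integer(), character())

  # 2. replay rule definitions along each path
  treats <- list()
  promotes <- list()
  for (p in paths) {
    verbs <- inter$verb[p]
    objs <- inter$object[p]
    actions <- character(length(p))
    rules <- character(length(p))
    actions[1] <- if (verbs[1] == "inhibits") "inactivates" else "activates"
    rules[1] <- if (verbs[1] == "inhibits") "R1a" else "R1b"
    alive <- TRUE
    for (k in seq_along(p)[-1]) {
      prev <- actions[k - 1]
      if (prev == "activates" && verbs[k] == "induces") {
        actions[k] <- "activates"; rules[k] <- "R2a"
      } else if (prev == "activates" && verbs[k] == "inhibits") {
        actions[k] <- "inactivates"; rules[k] <- "R2b"
      } else if (prev == "inactivates" && verbs[k] == "induces" &&
                 policy$inactivation_propagation) {
        actions[k] <- "inactivates"; rules[k] <- "R2c"
      } else if (prev == "inactivates" && verbs[k] == "inhibits" &&
                 policy$double_negation_rule) {
        actions[k] <- "activates"; rules[k] <- "R2d"
      } else {
        alive <- FALSE
        break
      }
    }
    if (!alive) next
    prefix <- lapply(seq_along(p), function(k) {
      list(drug = drug, action = actions[k], target = objs[k], step = k,
           rule = rules[k],
           support = sprintf("interaction(%s, %s, %s).",
                             inter$subject[p[k]], verbs[k], objs[k]))
    })
    last_a <- actions[length(p)]
    last_p <- objs[length(p)]
    s_end <- length(p) + 1L
    add_treat <- function(rule, support) {
      treats[[length(treats) + 1L]] <<- c(prefix, list(list(
        drug = drug, action = "treats", target = disease_class,
        step = s_end, rule = rule, support = sort(support)
      )))
    }
    add_promote <- function(rule, support) {
      promotes[[length(promotes) + 1L]] <<- c(prefix, list(list(
        drug = drug, action = "promotes", target = disease_class,
        step = s_end, rule = rule, support = sort(support)
      )))
    }

    if (last_a == "inactivates") {
      hit <- drel$protein == last_p & drel$expression_state == "overexpressed" &
        in_class(drel$disease)
      for (i in which(hit)) {
        add_treat("R3a", sprintf("relation(%s(%s), associated_with, %s).",
                                 drel$expression_state[i], drel$protein[i],
                                 drel$disease[i]))
      }
      if (last_p %in% onc) add_treat("R4", sprintf("oncogene(%s).", last_p))
      for (i in which(bprel$protein == last_p & bprel$bioprocess %in% pro_bp)) {
        add_treat("R6", c(
          sprintf("relation(%s, is_associated, %s).", bprel$protein[i],
                  bprel$bioprocess[i]),
          sprintf("cancer_promoting_bioprocess(%s).", bprel$bioprocess[i])
        ))
      }
    } else {
      hit <- drel$protein == last_p & drel$expression_state == "underexpressed" &
        in_class(drel$disease)
      for (i in which(hit)) {
        add_treat("R3b", sprintf("relation(%s(%s), associated_with, %s).",
                                 drel$expression_state[i], drel$protein[i],
                                 drel$disease[i]))
      }
      if (last_p %in% sup) add_treat("R5", sprintf("suppressor(%s).", last_p))
      for (i in which(bprel$protein == last_p & bprel$bioprocess %in% res_bp)) {
        add_treat("R7", c(
          sprintf("relation(%s, is_associated, %s).", bprel$protein[i],
                  bprel$bioprocess[i]),
          sprintf("cancer_resisting_bioprocess(%s).", bprel$bioprocess[i])
        ))
      }
    }

    if (policy$contradiction_mode != "ignore") {
      if (last_a == "activates") {
        if (last_p %in% onc) add_promote("C1", sprintf("oncogene(%s).", last_p))
        for (i in which(bprel$protein == last_p & bprel$bioprocess %in% pro_bp)) {
          add_promote("C3", c(
            sprintf("relation(%s, is_associated, %s).", bprel$protein[i],
                    bprel$bioprocess[i]),
            sprintf("cancer_promoting_bioprocess(%s).", bprel$bioprocess[i])
          ))
        }
        hit <- drel$protein == last_p & drel$expression_state == "overexpressed" &
          in_class(drel$disease)
        for (i in which(hit)) {
          add_promote("C5", sprintf("relation(%s(%s), associated_with, %s).",
                                    drel$expression_state[i], drel$protein[i],
                                    drel$disease[i]))
        }
      } else {
        if (last_p %in% sup) add_promote("C2", sprintf("suppressor(%s).", last_p))
        for (i in which(bprel$protein == last_p & bprel$bioprocess %in% res_bp)) {
          add_promote("C4", c(
            sprintf("relation(%s, is_associated, %s).", bprel$protein[i],
                    bprel$bioprocess[i]),
            sprintf("cancer_resisting_bioprocess(%s).", bprel$bioprocess[i])
          ))
        }
        hit <- drel$protein == last_p & drel$expression_state == "underexpressed" &
          in_class(drel$disease)
        for (i in which(hit)) {
          add_promote("C5", sprintf("relation(%s(%s), associated_with, %s).",
                                    drel$expression_state[i], drel$protein[i],
                                    drel$disease[i]))
        }
      }
    }
  }

  treats <- canonicalize_chains(treats)
  promotes <- canonicalize_chains(promotes)
  verdict <- if (length(promotes) == 0) {
    "clean"
  } else if (length(treats) > 0) "contradictory" else "promoting_only"
  returned <- if (policy$contradiction_mode == "block" &&
                  verdict == "contradictory") list() else treats
  list(
    chains = chains_to_tibble(returned),
    chain_info = chain_info_tibble(returned),
    promoting = chains_to_tibble(promotes),
    promoting_info = chain_info_tibble(promotes),
    verdict = verdict
  )
}
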