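#' @title Stepped forward-chaining inference of drug indications
#' @description
#' The engine derives `trigger(drug, action, target, step)` steps from a
#' knowledge base and strings them into inference chains that end in a
#' `treats` (or, for the anti-mechanism rules, a `promotes`) conclusion
#' about a disease class.
#'
#' Rule inventory:
#' * R1a/R1b — initial step: an antagonist drug-target edge triggers
#'   `inactivates`, an agonist edge triggers `activates` (step 1).
#' * R2a-R2c (+R2d) — propagation along signed protein-protein edges:
#'   an activated protein passes activation through `induces` (R2a) and
#'   inactivation through `inhibits` (R2b); an inactivated protein that
#'   normally induces a partner leaves it inactivated (R2c, policy
#'   `inactivation_propagation`); inhibiting an inhibitor activates the
#'   partner only under the optional double-negation reading (R2d,
#'   policy `double_negation_rule`).
#' * R3a/R3b — terminal by expression-disease association: inactivating
#'   a protein whose overexpression is associated with a disease in the
#'   class (R3a), or activating one whose underexpression is (R3b).
#' * R4/R5 — terminal by cancer-gene class: inactivating an oncogene
#'   (R4), activating a tumor suppressor (R5).
#' * R6/R7 — terminal by bioprocess class: inactivating a protein in a
#'   cancer-promoting bioprocess (R6), activating one in a
#'   cancer-resisting bioprocess (R7).
#' * C1-C5 — the sign-mirrored anti-mechanism rules deriving `promotes`
#'   (activating an oncogene, inactivating a suppressor, activating a
#'   promoting-bioprocess member, inactivating a resisting-bioprocess
#'   member, and the expression-state mirror of R3).
#'
#' A chain never revisits a protein and never exceeds
#' `max_depth + 1` triggers.  Chains with exactly 2 triggers are
#' classified `direct` (the conclusion comes straight from a drug
#' target), longer ones `indirect`.
#' @name engine
NULL

# trigger constructor: a plain list; chains are lists of triggers
new_trigger <- function(drug, action, target, step, rule, support) {
  list(drug = drug, action = action, target = target,
       step = as.integer(step), rule = rule, support = sort(support))
}

# precomputed lookup context for one (kb, disease_class, map)
build_engine_ctx <- function(kb, disease_class, map) {
  drel <- kb$disease_relations
  drel_in_class <- !is.na(map_disease_class(drel$disease, map)) &
    map_disease_class(drel$disease, map) == disease_class
  list(
    drugs = kb_drugs(kb),
    inter_subject = kb$interactions$subject,
    inter_verb = kb$interactions$verb,
    inter_object = kb$interactions$object,
    inter_str = interaction_string(kb$interactions$subject,
                                   kb$interactions$verb,
                                   kb$interactions$object),
    drel_protein = drel$protein,
    drel_state = drel$expression_state,
    drel_in_class = drel_in_class,
    drel_str = disease_relation_string(drel$protein, drel$expression_state,
                                       drel$disease),
    bprel_protein = kb$bioprocess_relations$protein,
    bprel_bp = kb$bioprocess_relations$bioprocess,
    bprel_str = bioprocess_relation_string(kb$bioprocess_relations$protein,
                                           kb$bioprocess_relations$bioprocess),
    oncogenes = kb_class_ids(kb, "oncogene"),
    suppressors = kb_class_ids(kb, "suppressor"),
    promoting_bps = kb_class_ids(kb, "promoting_bp"),
    resisting_bps = kb_class_ids(kb, "resisting_bp"),
    disease_class = disease_class
  )
}

#' Initial triggers of a drug (rules R1a/R1b)
#'
#' Each drug-target interaction of the drug yields one step-1 trigger:
#' `inhibits` edges trigger `inactivates` (R1a), `induces` edges trigger
#' `activates` (R1b).
#'
#' @param kb A `moa_kb` object.
#' @param drug A registered drug identifier.
#' @return A tibble of triggers (`drug`, `action`, `target`, `step`,
#'   `rule`, `support` list-column).
#' @examples
#' kb <- example_kb("dipyridamole")
#' initial_triggers(kb, "dipyridamole")
#' @export
initial_triggers <- function(kb, drug) {
  if (!drug %in% kb_drugs(kb)) {
    abort(sprintf("drug '%s' is not registered in the knowledge base", drug))
  }
  ctx <- build_engine_ctx(kb, "cancer", disease_class_map())
  triggers_to_tibble(initial_trigger_list(ctx, drug))
}

initial_trigger_list <- function(ctx, drug) {
  idx <- which(ctx$inter_subject == drug)
  lapply(idx, function(i) {
    if (ctx$inter_verb[[i]] == "inhibits") {
      new_trigger(drug, "inactivates", ctx$inter_object[[i]], 1L, "R1a",
                  ctx$inter_str[[i]])
    } else {
      new_trigger(drug, "activates", ctx$inter_object[[i]], 1L, "R1b",
                  ctx$inter_str[[i]])
    }
  })
}

# propagation transition: NULL when no rule fires
next_action_rule <- function(action, verb, policy) {
  if (action == "activates" && verb == "induces") {
    list(action = "activates", rule = "R2a")
  } else if (action == "activates" && verb == "inhibits") {
    list(action = "inactivates", rule = "R2b")
  } else if (action == "inactivates" && verb == "induces") {
    if (policy$inactivation_propagation) list(action = "inactivates", rule = "R2c")
  } else if (action == "inactivates" && verb == "inhibits") {
    if (policy$double_negation_rule) list(action = "activates", rule = "R2d")
  }
}

#' One propagation step (rules R2a-R2d)
#'
#' Extends a molecular trigger along the outgoing signed edges of its
#' target protein, skipping proteins in `visited` (the cycle guard: a
#' chain never re-triggers a protein it has already assigned an action).
#'
#' @param kb A `moa_kb` object.
#' @param trigger A one-row trigger tibble (or a list with fields
#'   `drug`, `action`, `target`, `step`) whose action is `activates` or
#'   `inactivates` and whose step is below `policy$max_depth`.
#' @param policy An [engine_policy()].
#' @param visited Character vector of proteins already on the chain;
#'   defaults to the trigger's own target.
#' @return A tibble of step `step + 1` triggers (possibly empty).
#' @export
propagate <- function(kb, trigger, policy = engine_policy(),
                      visited = NULL) {
  t <- as_trigger(trigger)
  stopifnot(t$action %in% c("activates", "inactivates"))
  ctx <- build_engine_ctx(kb, "cancer", disease_class_map())
  visited <- visited %||% t$target
  triggers_to_tibble(propagate_list(ctx, t, policy, visited))
}

propagate_list <- function(ctx, t, policy, visited) {
  idx <- which(ctx$inter_subject == t$target)
  out <- list()
  for (i in idx) {
    obj <- ctx$inter_object[[i]]
    if (obj %in% visited) next
    nx <- next_action_rule(t$action, ctx$inter_verb[[i]], policy)
    if (is.null(nx)) next
    out[[length(out) + 1L]] <- new_trigger(
      t$drug, nx$action, obj, t$step + 1L, nx$rule, ctx$inter_str[[i]]
    )
  }
  out
}

#' Terminal treats triggers (rules R3a-R7)
#'
#' Applies the terminal conditions to a molecular trigger and emits one
#' `treats` trigger per (rule, supporting fact) firing.
#'
#' @inheritParams propagate
#' @param disease_class Disease-class identifier of the goal.
#' @param map A [disease_class_map()] folding specific diseases into
#'   the class.
#' @return A tibble of `treats` triggers at step `step + 1`.
#' @export
terminal_triggers <- function(kb, trigger, disease_class = "cancer",
                              map = disease_class_map(disease_class)) {
  t <- as_trigger(trigger)
  stopifnot(t$action %in% c("activates", "inactivates"))
  ctx <- build_engine_ctx(kb, disease_class, map)
  triggers_to_tibble(terminal_list(ctx, t))
}

terminal_list <- function(ctx, t) {
  out <- list()
  emit <- function(rule, support) {
    out[[length(out) + 1L]] <<- new_trigger(
      t$drug, "treats", ctx$disease_class, t$step + 1L, rule, support
    )
  }
  p <- t$target
  if (t$action == "inactivates") {
    for (i in which(ctx$drel_protein == p & ctx$drel_state == "overexpressed" &
                      ctx$drel_in_class)) {
      emit("R3a", ctx$drel_str[[i]])
    }
    if (p %in% ctx$oncogenes) emit("R4", unary_fact_string("oncogene", p))
    for (i in which(ctx$bprel_protein == p &
                      ctx$bprel_bp %in% ctx$promoting_bps)) {
      emit("R6", c(ctx$bprel_str[[i]],
                   unary_fact_string("cancer_promoting_bioprocess", ctx$bprel_bp[[i]])))
    }
  } else {
    for (i in which(ctx$drel_protein == p & ctx$drel_state == "underexpressed" &
                      ctx$drel_in_class)) {
      emit("R3b", ctx$drel_str[[i]])
    }
    if (p %in% ctx$suppressors) emit("R5", unary_fact_string("suppressor", p))
    for (i in which(ctx$bprel_protein == p &
                      ctx$bprel_bp %in% ctx$resisting_bps)) {
      emit("R7", c(ctx$bprel_str[[i]],
                   unary_fact_string("cancer_resisting_bioprocess", ctx$bprel_bp[[i]])))
    }
  }
  out
}

#' Anti-mechanism promotes triggers (rules C1-C5)
#'
#' The sign mirror of the terminal rules: activating an oncogene (C1),
#' inactivating a suppressor (C2), activating a member of a
#' cancer-promoting bioprocess (C3), inactivating a member of a
#' cancer-resisting bioprocess (C4), and the expression-state mirror of
#' the disease-association rules (C5).  Each firing emits a `promotes`
#' trigger used by contradiction detection.
#'
#' @inheritParams terminal_triggers
#' @return A tibble of `promotes` triggers at step `step + 1`.
#' @export
contradiction_triggers <- function(kb, trigger, disease_class = "cancer",
                                   map = disease_class_map(disease_class)) {
  t <- as_trigger(trigger)
  stopifnot(t$action %in% c("activates", "inactivates"))
  ctx <- build_engine_ctx(kb, disease_class, map)
  triggers_to_tibble(contradiction_list(ctx, t))
}

contradiction_list <- function(ctx, t) {
  out <- list()
  emit <- function(rule, support) {
    out[[length(out) + 1L]] <<- new_trigger(
      t$drug, "promotes", ctx$disease_class, t$step + 1L, rule, support
    )
  }
  p <- t$target
  if (t$action == "activates") {
    if (p %in% ctx$oncogenes) emit("C1", unary_fact_string("oncogene", p))
    for (i in which(ctx$bprel_protein == p &
                      ctx$bprel_bp %in% ctx$promoting_bps)) {
      emit("C3", c(ctx$bprel_str[[i]],
                   unary_fact_string("cancer_promoting_bioprocess", ctx$bprel_bp[[i]])))
    }
    for (i in which(ctx$drel_protein == p & ctx$drel_state == "overexpressed" &
                      ctx$drel_in_class)) {
      emit("C5", ctx$drel_str[[i]])
    }
  } else {
    if (p %in% ctx$suppressors) emit("C2", unary_fact_string("suppressor", p))
    for (i in which(ctx$bprel_protein == p &
                      ctx$bprel_bp %in% ctx$resisting_bps)) {
      emit("C4", c(ctx$bprel_str[[i]],
                   unary_fact_string("cancer_resisting_bioprocess", ctx$bprel_bp[[i]])))
    }
    for (i in which(ctx$drel_protein == p & ctx$drel_state == "underexpressed" &
                      ctx$drel_in_class)) {
      emit("C5", ctx$drel_str[[i]])
    }
  }
  out
}

# depth-first enumeration of all chains for one drug
enumerate_chains <- function(ctx, drug, policy) {
  treats <- list()
  promotes <- list()
  walk <- function(path, visited) {
    t <- path[[length(path)]]
    for (tt in terminal_list(ctx, t)) {
      treats[[length(treats) + 1L]] <<- c(path, list(tt))
    }
    if (policy$contradiction_mode != "ignore") {
      for (tt in contradiction_list(ctx, t)) {
        promotes[[length(promotes) + 1L]] <<- c(path, list(tt))
      }
    }
    if (t$step < policy$max_depth) {
      for (tt in propagate_list(ctx, t, policy, visited)) {
        walk(c(path, list(tt)), c(visited, tt$target))
      }
    }
  }
  for (t1 in initial_trigger_list(ctx, drug)) {
    walk(list(t1), t1$target)
  }
  list(treats = canonicalize_chains(treats),
       promotes = canonicalize_chains(promotes))
}

# one sortable signature per chain; used for dedup, ordering and
# engine-vs-oracle comparison
chain_key <- function(chain) {
  paste(
    vapply(chain, function(t) {
      sprintf("%d:%s:%s:%s[%s]", t$step, t$action, t$target, t$rule,
              paste(t$support, collapse = "; "))
    }, character(1)),
    collapse = " | "
  )
}

canonicalize_chains <- function(chains) {
  if (length(chains) == 0) return(chains)
  keys <- vapply(chains, chain_key, character(1))
  chains <- chains[!duplicated(keys)]
  keys <- keys[!duplicated(keys)]
  chains[order(lengths(chains), keys, method = "radix")]
}

triggers_to_tibble <- function(triggers) {
  if (length(triggers) == 0) {
    return(tibble(drug = character(), action = character(),
                  target = character(), step = integer(),
                  rule = character(), support = list()))
  }
  tibble(
    drug = map_chr(triggers, "drug"),
    action = map_chr(triggers, "action"),
    target = map_chr(triggers, "target"),
    step = map_int(triggers, "step"),
    rule = map_chr(triggers, "rule"),
    support = map(triggers, "support")
  )
}

as_trigger <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1)
    x <- as.list(x)
    if (is.list(x$support)) x$support <- x$support[[1]]
  }
  x
}

chains_to_tibble <- function(chains) {
  if (length(chains) == 0) {
    return(tibble(chain = integer(), drug = character(), step = integer(),
                  action = character(), target = character(),
                  rule = character(), support = list()))
  }
  out <- imap(chains, function(ch, i) {
    tb <- triggers_to_tibble(ch)
    tb$chain <- as.integer(i)
    tb
  })
  select(list_rbind(out), "chain", "drug", "step", "action", "target",
         "rule", "support")
}

chain_info_tibble <- function(chains) {
  if (length(chains) == 0) {
    return(tibble(chain = integer(), n_steps = integer(),
                  classification = character(), terminal_rule = character()))
  }
  tibble(
    chain = seq_along(chains),
    n_steps = lengths(chains),
    classification = ifelse(lengths(chains) == 2L, "direct", "indirect"),
    terminal_rule = map_chr(chains, function(ch) ch[[length(ch)]]$rule)
  )
}

#' Infer treatment chains for one drug
#'
#' Exhaustively enumerates every inference chain for `drug`: initial
#' triggers (R1), propagation steps (R2) bounded by
#' `policy$max_depth` and by the no-revisit cycle guard, terminal
#' treats rules (R3-R7) and — unless `contradiction_mode = "ignore"` —
#' the anti-mechanism promotes rules (C1-C5).  Chains identical in
#' their full trigger sequence are one chain; the same conclusion via
#' different supporting facts yields distinct chains, all reported.
#' Chains are ordered by (length, trigger-sequence) for
#' reproducibility.
#'
#' Under `contradiction_mode = "block"`, a drug for which any promotes
#' chain derives returns zero treats chains; the suppressed chains stay
#' available in the contradiction report.
#'
#' @param kb A `moa_kb` object.
#' @param drug A registered drug identifier.
#' @param disease_class Disease-class identifier of the goal.
#' @param map A [disease_class_map()].
#' @param policy An [engine_policy()].
#' @return A `moa_inference` object with elements `drug`, `chains`
#'   (trigger-level tibble of the returned chains), `chain_info`
#'   (per-chain classification), `report` (the contradiction report:
#'   `treating`, `promoting`, `verdict`), `policy`, `disease_class`.
#' @examples
#' kb <- example_kb("tazarotene")
#' fit <- infer(kb, "tazarotene")
#' tidy(fit)
#' glance(fit)
#' @export
infer <- function(kb, drug, disease_class = "cancer",
                  map = disease_class_map(disease_class),
                  policy = engine_policy()) {
  if (!drug %in% kb_drugs(kb)) {
    abort(sprintf("drug '%s' is not registered in the knowledge base", drug))
  }
  ctx <- build_engine_ctx(kb, disease_class, map)
  infer_ctx(ctx, drug, disease_class, policy)
}

infer_ctx <- function(ctx, drug, disease_class, policy) {
  res <- enumerate_chains(ctx, drug, policy)
  verdict <- if (length(res$promotes) == 0) {
    "clean"
  } else if (length(res$treats) > 0) {
    "contradictory"
  } else {
    "promoting_only"
  }
  blocked <- policy$contradiction_mode == "block" && verdict == "contradictory"
  returned <- if (blocked) list() else res$treats
  structure(
    list(
      drug = drug,
      disease_class = disease_class,
      chains = chains_to_tibble(returned),
      chain_info = chain_info_tibble(returned),
      report = list(
        drug = drug,
        treating = chains_to_tibble(res$treats),
        treating_info = chain_info_tibble(res$treats),
        promoting = chains_to_tibble(res$promotes),
        promoting_info = chain_info_tibble(res$promotes),
        verdict = verdict
      ),
      blocked = blocked,
      policy = policy
    ),
    class = "moa_inference"
  )
}

#' Screen every registered drug
#'
#' Applies [infer()] to each drug in the knowledge base, in
#' lexicographic order.
#'
#' @inheritParams infer
#' @return A `moa_screen` object: `results` (named list of
#'   `moa_inference` objects) and `summary` (one row per drug: chain
#'   counts by classification and the contradiction verdict).
#' @examples
#' kb <- example_kb("dipyridamole")
#' screen <- infer_all(kb)
#' glance(screen)
#' @export
infer_all <- function(kb, disease_class = "cancer",
                      map = disease_class_map(disease_class),
                      policy = engine_policy()) {
  drugs <- sort(kb_drugs(kb), method = "radix")
  ctx <- build_engine_ctx(kb, disease_class, map)
  results <- lapply(drugs, function(d) infer_ctx(ctx, d, disease_class, policy))
  names(results) <- drugs
  summary <- if (length(results)) {
    list_rbind(map(results, glance.moa_inference))
  } else {
    tibble(drug = character(), n_chains = integer(), n_direct = integer(),
           n_indirect = integer(), n_promoting = integer(),
           verdict = character(), blocked = logical())
  }
  structure(
    list(results = results, summary = summary,
         disease_class = disease_class, policy = policy),
    class = "moa_screen"
  )
}

#' Drugs with at least one treats chain
#'
#' @param screen A `moa_screen` from [infer_all()].
#' @return Sorted character vector of inferred drugs.
#' @export
inferred_drugs <- function(screen) {
  sort(screen$summary$drug[screen$summary$n_chains > 0], method = "radix")
}

#' @export
print.moa_inference <- function(x, ...) {
  cat(sprintf("<moa_inference> %s -> %s: %d chain(s), verdict %s\n",
              x$drug, x$disease_class, nrow(x$chain_info),
              x$report$verdict))
  if (nrow(x$chains) > 0) {
    for (i in x$chain_info$chain) {
      steps <- filter(x$chains, .data$chain == i)
      cat(sprintf("  [%s] %s\n", x$chain_info$classification[[i]],
                  paste(sprintf("%s(%s)@%d", steps$action, steps$target,
                                steps$step), collapse = " -> ")))
    }
  }
  if (x$blocked) {
    cat(sprintf("  (blocked: %d treats chain(s) suppressed by contradiction)\n",
                nrow(x$report$treating_info)))
  }
  invisible(x)
}

#' @export
print.moa_screen <- function(x, ...) {
  cat(sprintf("<moa_screen> %d drug(s) screened against %s, %d with chains\n",
              nrow(x$summary), x$disease_class, length(inferred_drugs(x))))
  print(x$summary, ...)
  invisible(x)
}
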