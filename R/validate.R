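#' Re-validate inference chains against a knowledge base
#'
#' An independent soundness check: each chain is re-derived step by
#' step by direct fact lookup, without using the engine's traversal.
#' A chain is valid when its steps are consecutive from 1, no protein
#' is revisited, every support fact is present in the knowledge base,
#' each rule's precondition holds (initial rule verb, propagation
#' transition and its policy gate, terminal condition on the final
#' molecular trigger), and the terminal action is `treats` or
#' `promotes` on the disease class.
#'
#' @param kb A `moa_kb` object.
#' @param chains Trigger-level chains tibble (`chain`, `drug`, `step`,
#'   `action`, `target`, `rule`, `support`), e.g. `infer()$chains` or
#'   chains read back from the JSON the CLI writes.
#' @param disease_class,map,policy As for [infer()].
#' @return A tibble with one row per chain: `chain`, `drug`, `valid`,
#'   `reason` (`NA` when valid).
#' @export
validate_chains <- function(kb, chains, disease_class = "cancer",
                            map = disease_class_map(disease_class),
                            policy = engine_policy()) {
  facts <- strsplit(serialize_facts(kb), "\n")[[1]]
  out <- map(split(seq_len(nrow(chains)), chains$chain), function(idx) {
    ch <- chains[idx, ]
    ch <- ch[order(ch$step), ]
    reason <- validate_one_chain(ch, facts, disease_class, map, policy)
    tibble(chain = ch$chain[[1]], drug = ch$drug[[1]],
           valid = is.na(reason), reason = reason)
  })
  list_rbind(out)
}

validate_one_chain <- function(ch, facts, disease_class, map, policy) {
  n <- nrow(ch)
  if (n < 2) return("a chain needs at least an initial and a terminal trigger")
  if (!identical(ch$step, seq_len(n))) return("steps are not consecutive from 1")
  if (anyDuplicated(ch$target[-n])) return("a protein is revisited")
  if (!ch$action[[n]] %in% c("treats", "promotes")) {
    return("last trigger is not a treats/promotes conclusion")
  }
  if (ch$target[[n]] != disease_class) {
    return(sprintf("terminal targets '%s', expected disease class '%s'",
                   ch$target[[n]], disease_class))
  }
  if (any(ch$action[-n] == "treats")) return("treats before the final step")
  for (supp in unlist(ch$support)) {
    if (!supp %in% facts) return(sprintf("support fact not in KB: %s", supp))
  }

  # initial step
  want_verb <- switch(ch$rule[[1]], R1a = "inhibits", R1b = "induces",
                      return(sprintf("step 1 must use R1a/R1b, got %s", ch$rule[[1]])))
  want_act <- if (want_verb == "inhibits") "inactivates" else "activates"
  if (ch$action[[1]] != want_act) return("step-1 action inconsistent with its rule")
  if (!interaction_string(ch$drug[[1]], want_verb, ch$target[[1]]) %in% facts) {
    return("step-1 drug-target fact missing")
  }

  # propagation steps
  if (n > 2) {
    for (k in 2:(n - 1)) {
      tr <- switch(ch$rule[[k]],
        R2a = list(prev = "activates", verb = "induces", act = "activates", ok = TRUE),
        R2b = list(prev = "activates", verb = "inhibits", act = "inactivates", ok = TRUE),
        R2c = list(prev = "inactivates", verb = "induces", act = "inactivates",
                   ok = policy$inactivation_propagation),
        R2d = list(prev = "inactivates", verb = "inhibits", act = "activates",
                   ok = policy$double_negation_rule),
        return(sprintf("step %d must use a propagation rule, got %s", k, ch$rule[[k]]))
      )
      if (!tr$ok) return(sprintf("rule %s disabled by policy", ch$rule[[k]]))
      if (ch$action[[k - 1]] != tr$prev || ch$action[[k]] != tr$act) {
        return(sprintf("step %d action transition inconsistent with %s", k, ch$rule[[k]]))
      }
      if (!interaction_string(ch$target[[k - 1]], tr$verb, ch$target[[k]]) %in% facts) {
        return(sprintf("step-%d interaction fact missing", k))
      }
    }
  }
  if (n > policy$max_depth + 1L) return("chain exceeds max_depth + 1 triggers")

  # terminal step
  prev_act <- ch$action[[n - 1]]
  prev_p <- ch$target[[n - 1]]
  rule <- ch$rule[[n]]
  supp <- sort(unlist(ch$support[[n]]))
  need <- function(cond, msg) if (!cond) msg else NA_character_
  rel_in_class <- function(state) {
    m <- regmatches(supp[[1]], regexec(
      sprintf("^relation\\(%s\\(([a-z0-9_]+)\\), associated_with, ([a-z0-9_]+)\\)\\.$",
              state), supp[[1]]))[[1]]
    length(m) == 3 && m[[2]] == prev_p &&
      identical(map_disease_class(m[[3]], map), disease_class)
  }
  bp_ok <- function(cls_pred) {
    length(supp) == 2 &&
      grepl(sprintf("^relation\\(%s, is_associated, ([a-z0-9_]+)\\)\\.$", prev_p),
            supp[[2]]) &&
      sub(sprintf("^relation\\(%s, is_associated, ([a-z0-9_]+)\\)\\.$", prev_p),
          "\\1", supp[[2]]) ==
        sub(sprintf("^%s\\(([a-z0-9_]+)\\)\\.$", cls_pred), "\\1", supp[[1]]) &&
      grepl(sprintf("^%s\\(", cls_pred), supp[[1]])
  }
  ok <- switch(rule,
    R3a = need(ch$action[[n]] == "treats" && prev_act == "inactivates" &&
                 rel_in_class("overexpressed"), "R3a precondition fails"),
    R3b = need(ch$action[[n]] == "treats" && prev_act == "activates" &&
                 rel_in_class("underexpressed"), "R3b precondition fails"),
    R4 = need(ch$action[[n]] == "treats" && prev_act == "inactivates" &&
                identical(supp, unary_fact_string("oncogene", prev_p)),
              "R4 precondition fails"),
    R5 = need(ch$action[[n]] == "treats" && prev_act == "activates" &&
                identical(supp, unary_fact_string("suppressor", prev_p)),
              "R5 precondition fails"),
    R6 = need(ch$action[[n]] == "treats" && prev_act == "inactivates" &&
                bp_ok("cancer_promoting_bioprocess"), "R6 precondition fails"),
    R7 = need(ch$action[[n]] == "treats" && prev_act == "activates" &&
                bp_ok("cancer_resisting_bioprocess"), "R7 precondition fails"),
    C1 = need(ch$action[[n]] == "promotes" && prev_act == "activates" &&
                identical(supp, unary_fact_string("oncogene", prev_p)),
              "C1 precondition fails"),
    C2 = need(ch$action[[n]] == "promotes" && prev_act == "inactivates" &&
                identical(supp, unary_fact_string("suppressor", prev_p)),
              "C2 precondition fails"),
    C3 = need(ch$action[[n]] == "promotes" && prev_act == "activates" &&
                bp_ok("cancer_promoting_bioprocess"), "C3 precondition fails"),
    C4 = need(ch$action[[n]] == "promotes" && prev_act == "inactivates" &&
                bp_ok("cancer_resisting_bioprocess"), "C4 precondition fails"),
    C5 = need(ch$action[[n]] == "promotes" &&
                ((prev_act == "activates" && rel_in_class("overexpressed")) ||
                   (prev_act == "inactivates" && rel_in_class("underexpressed"))),
              "C5 precondition fails"),
    sprintf("unknown terminal rule %s", rule)
  )
  ok
}
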