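#' Tidy an inference result
#'
#' Returns one row per trigger of each returned chain, joined with its
#' chain's classification and terminal rule.  The `support` list-column
#' holds the fact strings consumed by each rule firing.
#'
#' @param x A `moa_inference` object.
#' @param ... Unused.
#' @return A tibble with columns `drug`, `chain`, `step`, `action`,
#'   `target`, `rule`, `support`, `classification`, `terminal_rule`.
#' @export
tidy.moa_inference <- function(x, ...) {
  left_join(x$chains, x$chain_info, by = "chain")
}

#' One-row summary of an inference result
#'
#' @param x A `moa_inference` object.
#' @param ... Unused.
#' @return A tibble with the drug, chain counts by classification, the
#'   contradiction verdict and whether block mode suppressed chains.
#' @export
glance.moa_inference <- function(x, ...) {
  tibble(
    drug = x$drug,
    n_chains = nrow(x$chain_info),
    n_direct = sum(x$chain_info$classification == "direct"),
    n_indirect = sum(x$chain_info$classification == "indirect"),
    n_promoting = nrow(x$report$promoting_info),
    verdict = x$report$verdict,
    blocked = x$blocked
  )
}

#' Tidy a drug screen
#'
#' @param x A `moa_screen` object from [infer_all()].
#' @param ... Unused.
#' @return Trigger-level tibble across all screened drugs (drugs with
#'   no chains contribute no rows).
#' @export
tidy.moa_screen <- function(x, ...) {
  list_rbind(map(x$results, tidy.moa_inference))
}

#' One-row summary of a drug screen
#'
#' @param x A `moa_screen` object.
#' @param ... Unused.
#' @return A tibble with the number of drugs screened, inferred, direct
#'   and indirect chain totals, and contradiction counts.
#' @export
glance.moa_screen <- function(x, ...) {
  s <- x$summary
  tibble(
    n_drugs = nrow(s),
    n_inferred = sum(s$n_chains > 0),
    n_chains = sum(s$n_chains),
    n_direct = sum(s$n_direct),
    n_indirect = sum(s$n_indirect),
    n_contradictory = sum(s$verdict == "contradictory"),
    n_blocked = sum(s$blocked)
  )
}

#' Tidy an ablation result
#'
#' @param x A `moa_ablation` object from [source_ablation()].
#' @param ... Unused.
#' @return The per-subset metrics table (one row per source subset plus
#'   the full-KB row).
#' @export
tidy.moa_ablation <- function(x, ...) {
  select(x$table, -"inferred")
}

#' Full-knowledge-base row of an ablation result
#'
#' @param x A `moa_ablation` object.
#' @param ... Unused.
#' @return A one-row tibble: the metrics computed on the complete KB.
#' @export
glance.moa_ablation <- function(x, ...) {
  select(filter(x$table, .data$sources == "all"), -"inferred")
}
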