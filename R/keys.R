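#' Canonical chain signatures
#'
#' Renders each chain of a trigger-level chains tibble (as returned in
#' the `chains` element of [infer()] results, by [oracle_infer()], or as
#' planted ground truth from [generate_kb()]) into one canonical string
#' per chain: `step:action:target:rule[support; ...]` segments joined
#' with `" | "`.  Two chains are the same inference exactly when their
#' signatures are equal, so signature sets are the currency of
#' engine-vs-oracle and planted-recovery comparisons.
#'
#' @param chains A tibble with columns `chain`, `step`, `action`,
#'   `target`, `rule`, `support`.
#' @return Character vector, one signature per chain, sorted.
#' @export
chain_keys <- function(chains) {
  if (nrow(chains) == 0) return(character())
  segs <- sprintf("%d:%s:%s:%s[%s]", chains$step, chains$action,
                  chains$target, chains$rule,
                  map_chr(chains$support, paste, collapse = "; "))
  keys <- vapply(split(segs, chains$chain), paste, character(1),
                 collapse = " | ")
  sort(unname(keys), method = "radix")
}
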