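#' Engine policy: depth, contradiction handling, propagation variants
#'
#' Collects the tunable knobs of the forward-chaining engine.
#'
#' `max_depth` bounds the number of molecular steps a chain may take
#' before its terminal treats/promotes step; a treats chain therefore
#' has at most `max_depth + 1` triggers and needs at least 2.
#'
#' `contradiction_mode` governs the anti-mechanism (promotes) rules:
#' `"block"` (default) suppresses every treats chain of a drug for which
#' a promotes chain also derives, `"flag"` returns the treats chains
#' alongside the contradiction report, `"ignore"` skips the
#' anti-mechanism rules altogether.
#'
#' `inactivation_propagation` enables the loss-of-activator reading of
#' signal propagation (an inactivated protein that normally induces a
#' second protein leaves that protein inactivated); it is on by default.
#' `double_negation_rule` enables inferring activation from inhibiting
#' an inhibitor, which presumes basal activity of the downstream
#' protein; it is off by default.
#'
#' @param max_depth Positive integer, at least 2.
#' @param contradiction_mode One of `"block"`, `"flag"`, `"ignore"`.
#' @param double_negation_rule Logical.
#' @param inactivation_propagation Logical.
#' @return A `moa_policy` object.
#' @export
engine_policy <- function(max_depth = 5L,
                          contradiction_mode = c("block", "flag", "ignore"),
                          double_negation_rule = FALSE,
                          inactivation_propagation = TRUE) {
  contradiction_mode <- match.arg(contradiction_mode)
  max_depth <- as.integer(max_depth)
  if (is.na(max_depth) || max_depth < 2L) {
    abort("max_depth must be an integer >= 2 (a treats chain needs two steps)")
  }
  structure(
    list(
      max_depth = max_depth,
      contradiction_mode = contradiction_mode,
      double_negation_rule = isTRUE(double_negation_rule),
      inactivation_propagation = isTRUE(inactivation_propagation)
    ),
    class = "moa_policy"
  )
}

#' @export
print.moa_policy <- function(x, ...) {
  cat(sprintf(
    "<moa_policy> max_depth=%d, contradiction_mode=%s, double_negation=%s, inactivation_propagation=%s\n",
    x$max_depth, x$contradiction_mode, x$double_negation_rule,
    x$inactivation_propagation
  ))
  invisible(x)
}
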