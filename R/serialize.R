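#' Serialize a knowledge base to the fact dialect
#'
#' The inverse of [parse_fact_file()]: emits every entity registration,
#' class assertion and fact as one `predicate(args).` line, lowercase
#' atoms, deterministically ordered (byte order on the rendered lines,
#' which sorts by predicate name and then lexicographically by
#' arguments).  The output is stable under re-serialization and is valid
#' input for a stock answer-set-programming grounder, which is what
#' [export_asp()] builds on.
#'
#' @param kb A `moa_kb` object.
#' @return A single character scalar; `""` for an empty knowledge base.
#' @examples
#' kb <- knowledge_base(interactions = data.frame(
#'   subject = "egf", verb = "induces", object = "erbb2"
#' ), proteins = c("egf", "erbb2"), auto_register = TRUE)
#' cat(serialize_facts(kb))
#' @export
serialize_facts <- function(kb) {
  ent <- kb$entities
  cls <- kb$classes
  lines <- c(
    unary_fact_string(ENTITY_PREDICATES[ent$type], ent$id),
    unary_fact_string(CLASS_PREDICATES[cls$class], cls$id),
    interaction_string(kb$interactions$subject, kb$interactions$verb,
                       kb$interactions$object),
    disease_relation_string(kb$disease_relations$protein,
                            kb$disease_relations$expression_state,
                            kb$disease_relations$disease),
    bioprocess_relation_string(kb$bioprocess_relations$protein,
                               kb$bioprocess_relations$bioprocess)
  )
  if (length(lines) == 0) return("")
  paste0(paste(sort(unique(lines), method = "radix"), collapse = "\n"), "\n")
}

#' Write a knowledge base to a fact file
#'
#' @param kb A `moa_kb` object.
#' @param path Output path (conventionally `.lp`).
#' @return `path`, invisibly.
#' @export
write_kb <- function(kb, path) {
  writeLines(sub("\n$", "", serialize_facts(kb)), path)
  invisible(path)
}

#' Export a complete answer-set program for cross-checking
#'
#' Combines the serialized facts with the packaged static rule file
#' (the seven mechanism-of-action rules plus the contradiction rules in
#' clingo syntax) into a single self-contained program whose
#' `trigger/4` atoms can be compared against the native engine's output
#' drug-by-drug.
#'
#' @param kb A `moa_kb` object.
#' @param path Optional output path; when `NULL` the program text is
#'   returned only.
#' @param max_depth Step bound substituted into the rule file's
#'   `#const max_depth`.
#' @return The program text, invisibly when `path` is given.
#' @export
export_asp <- function(kb, path = NULL, max_depth = 5L) {
  rules_path <- system.file("extdata", "moa_rules.lp", package = "drugmoa")
  rules <- paste(readLines(rules_path, warn = FALSE), collapse = "\n")
  rules <- sub("#const max_depth = [0-9]+\\.",
               sprintf("#const max_depth = %d.", as.integer(max_depth)), rules)
  program <- paste0(
    "% facts\n", serialize_facts(kb), "\n", rules, "\n"
  )
  if (!is.null(path)) {
    writeLines(sub("\n$", "", program), path)
    return(invisible(program))
  }
  program
}
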