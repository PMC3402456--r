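#' Normalize an identifier to a logic atom
#'
#' Identifiers from external tables (gene symbols, drug names, GO term
#' labels) are normalized to the lowercase atom form used throughout the
#' fact dialect: lowercased, every run of non-alphanumeric characters
#' replaced by a single underscore, leading/trailing underscores trimmed.
#' `"Dipyridamole"` becomes `"dipyridamole"`, `"positive regulation of
#' cell proliferation"` becomes `"positive_regulation_of_cell_proliferation"`.
#'
#' @param x Character vector of raw identifiers.
#' @return Character vector of atoms.
#' @examples
#' normalize_atom(c("Dipyridamole", "RAR-alpha", " TP53 "))
#' @export
normalize_atom <- function(x) {
  x <- tolower(str_trim(as.character(x)))
  x <- gsub("[^a-z0-9]+", "_", x)
  gsub("^_+|_+$", "", x)
}

is_atom <- function(x) {
  grepl("^[a-z][a-z0-9_]*$", x)
}

# Rendered fact strings (the .lp surface syntax); these are also the
# support-fact references attached to triggers.
interaction_string <- function(subject, verb, object) {
  sprintf("interaction(%s, %s, %s).", subject, verb, object)
}

disease_relation_string <- function(protein, state, disease) {
  sprintf("relation(%s(%s), associated_with, %s).", state, protein, disease)
}

bioprocess_relation_string <- function(protein, bioprocess) {
  sprintf("relation(%s, is_associated, %s).", protein, bioprocess)
}

unary_fact_string <- function(predicate, id) {
  sprintf("%s(%s).", predicate, id)
}

CLASS_PREDICATES <- c(
  oncogene      = "oncogene",
  suppressor    = "suppressor",
  promoting_bp  = "cancer_promoting_bioprocess",
  resisting_bp  = "cancer_resisting_bioprocess"
)

ENTITY_PREDICATES <- c(
  drug       = "drug",
  protein    = "protein",
  disease    = "disease",
  bioprocess = "bioprocess"
)

SOURCE_TAGS <- c("drugbank", "cancer_genes", "go", "text_mining", "other")
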