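#' Load a drug-target table into interaction facts
#'
#' Converts a DrugBank-style table of pharmacological actions into
#' drug-target interaction facts: agonists induce and antagonists
#' inhibit their target.  Identifiers are normalized to lowercase atoms
#' with [normalize_atom()].  Rows whose action is not in the synonym map
#' are rejected and reported with a warning; exact duplicate rows are
#' dropped silently (the count is reported with a message).
#'
#' @param rows Data frame with columns `drug`, `target`, `action`.
#' @param action_map Named character vector mapping action values to
#'   interaction verbs.
#' @return A tibble of interactions (`subject`, `verb`, `object`,
#'   `source = "drugbank"`, `evidence`), ready for [knowledge_base()].
#'   Rejected rows are attached as the `"rejected"` attribute.
#' @examples
#' load_drug_target_table(data.frame(
#'   drug = "Dipyridamole", target = "ADA", action = "antagonist"
#' ))
#' @export
load_drug_target_table <- function(rows,
                                   action_map = c(agonist = "induces",
                                                  antagonist = "inhibits")) {
  rows <- as_tibble(as.data.frame(rows))
  if (nrow(rows) == 0) {
    return(tibble(subject = character(), verb = character(),
                  object = character(), source = character(),
                  evidence = character()))
  }
  missing_cols <- setdiff(c("drug", "target", "action"), names(rows))
  if (length(missing_cols)) {
    abort(sprintf("drug-target table is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  action <- tolower(str_trim(as.character(rows$action)))
  known <- action %in% names(action_map)
  if (any(!known)) {
    warn(sprintf(
      "rejected %d row(s) with unmapped action value(s): %s",
      sum(!known), paste(unique(action[!known]), collapse = ", ")
    ))
  }
  out <- tibble(
    subject = normalize_atom(rows$drug[known]),
    verb = unname(action_map[action[known]]),
    object = normalize_atom(rows$target[known]),
    source = "drugbank",
    evidence = if ("evidence" %in% names(rows)) {
      as.character(rows$evidence[known])
    } else NA_character_
  )
  n_before <- nrow(out)
  out <- distinct(out, .data$subject, .data$verb, .data$object, .keep_all = TRUE)
  if (nrow(out) < n_before) {
    inform(sprintf("dropped %d duplicate drug-target row(s)", n_before - nrow(out)))
  }
  attr(out, "rejected") <- rows[!known, , drop = FALSE]
  out
}

#' Load a mixed relation table into typed fact lists
#'
#' Routes text-mined triples by verb: `induces`/`inhibits` rows become
#' protein-protein interactions, `associated_with` rows become
#' expression-state-qualified gene-disease relations (the qualifier is
#' mandatory — the terminal inference rules are defined only for over-
#' and under-expression), and `is_associated` rows become
#' gene-bioprocess relations.
#'
#' @param rows Data frame with columns `subject`, `verb`, `object`,
#'   `qualifier` (empty/`NA`/`"-"` except for `associated_with` rows)
#'   and optionally `source` and `evidence`.
#' @return A list with tibbles `interactions`, `disease_relations`,
#'   `bioprocess_relations`.
#' @examples
#' load_relation_table(data.frame(
#'   subject = c("AMACR", "TNF"),
#'   verb = c("associated_with", "inhibits"),
#'   object = c("gastric cancer", "PPARG"),
#'   qualifier = c("overexpressed", "-")
#' ))
#' @export
load_relation_table <- function(rows) {
  empty <- list(
    interactions = tibble(subject = character(), verb = character(),
                          object = character(), source = character(),
                          evidence = character()),
    disease_relations = tibble(protein = character(),
                               expression_state = character(),
                               disease = character(), source = character(),
                               evidence = character()),
    bioprocess_relations = tibble(protein = character(),
                                  bioprocess = character(),
                                  source = character())
  )
  rows <- as_tibble(as.data.frame(rows))
  if (nrow(rows) == 0) return(empty)
  missing_cols <- setdiff(c("subject", "verb", "object"), names(rows))
  if (length(missing_cols)) {
    abort(sprintf("relation table is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  qual <- if ("qualifier" %in% names(rows)) {
    q <- tolower(str_trim(as.character(rows$qualifier)))
    q[q %in% c("", "-")] <- NA_character_
    q
  } else rep(NA_character_, nrow(rows))
  verb <- tolower(str_trim(as.character(rows$verb)))
  src <- if ("source" %in% names(rows)) as.character(rows$source) else "text_mining"
  src[is.na(src)] <- "text_mining"
  evid <- if ("evidence" %in% names(rows)) as.character(rows$evidence) else NA_character_
  if (length(src) == 1) src <- rep(src, nrow(rows))
  if (length(evid) == 1) evid <- rep(evid, nrow(rows))

  bad_verb <- !verb %in% c("induces", "inhibits", "associated_with", "is_associated")
  if (any(bad_verb)) {
    abort(sprintf("unknown verb(s) in relation table: %s",
                  paste(unique(verb[bad_verb]), collapse = ", ")))
  }
  is_assoc_dis <- verb == "associated_with"
  if (any(is_assoc_dis & is.na(qual))) {
    abort(sprintf(
      "%d associated_with row(s) lack an expression-state qualifier; the terminal rules require overexpressed/underexpressed",
      sum(is_assoc_dis & is.na(qual))
    ))
  }
  bad_qual <- is_assoc_dis & !qual %in% c("overexpressed", "underexpressed")
  if (any(bad_qual)) {
    abort(sprintf("unknown qualifier(s): %s",
                  paste(unique(qual[bad_qual]), collapse = ", ")))
  }
  if (any(!is_assoc_dis & !is.na(qual))) {
    abort("expression-state qualifiers are only allowed on associated_with rows")
  }

  is_ppi <- verb %in% c("induces", "inhibits")
  is_bp <- verb == "is_associated"
  list(
    interactions = tibble(
      subject = normalize_atom(rows$subject[is_ppi]),
      verb = verb[is_ppi],
      object = normalize_atom(rows$object[is_ppi]),
      source = src[is_ppi],
      evidence = evid[is_ppi]
    ),
    disease_relations = tibble(
      protein = normalize_atom(rows$subject[is_assoc_dis]),
      expression_state = qual[is_assoc_dis],
      disease = normalize_atom(rows$object[is_assoc_dis]),
      source = src[is_assoc_dis],
      evidence = evid[is_assoc_dis]
    ),
    bioprocess_relations = tibble(
      protein = normalize_atom(rows$subject[is_bp]),
      bioprocess = normalize_atom(rows$object[is_bp]),
      source = src[is_bp]
    )
  )
}

#' Load labeled drug sets from a table
#'
#' @param rows Data frame with columns `drug` and `label`
#'   (`"original"` or `"trial"`).
#' @param universe Character vector of all screened drugs.
#' @return A [label_sets()] object.
#' @export
load_labels <- function(rows, universe) {
  rows <- as_tibble(as.data.frame(rows))
  bad <- setdiff(unique(rows$label), c("original", "trial"))
  if (length(bad)) {
    abort(sprintf("unknown label(s): %s", paste(bad, collapse = ", ")))
  }
  label_sets(
    original = normalize_atom(rows$drug[rows$label == "original"]),
    trial = normalize_atom(rows$drug[rows$label == "trial"]),
    universe = normalize_atom(universe)
  )
}
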