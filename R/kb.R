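#' Build a knowledge base of drug-mechanism facts
#'
#' The knowledge base is the single container every other function in the
#' package consumes.  It holds an entity registry (drugs, proteins,
#' diseases, bioprocesses), class assertions (oncogenes, tumor
#' suppressors, cancer-promoting and cancer-resisting bioprocesses) and
#' three fact tables: signed directed interactions (drug-target and
#' protein-protein), expression-state-qualified gene-disease relations,
#' and gene-bioprocess relations.  Every fact carries a provenance tag
#' used by [source_ablation()].
#'
#' With `auto_register = TRUE` (the default) identifiers referenced by
#' facts are registered automatically: an undeclared interaction subject
#' that never appears as a protein elsewhere is taken to be a drug, all
#' other undeclared protein slots become proteins, and diseases and
#' bioprocesses named by relations are registered as such.  Class
#' assertions always register their entity.
#'
#' @param interactions Data frame with columns `subject`, `verb`
#'   (`"induces"`/`"inhibits"`), `object`, and optionally `source` and
#'   `evidence`.
#' @param disease_relations Data frame with columns `protein`,
#'   `expression_state` (`"overexpressed"`/`"underexpressed"`),
#'   `disease`, and optionally `source` and `evidence`.
#' @param bioprocess_relations Data frame with columns `protein`,
#'   `bioprocess`, and optionally `source`.
#' @param drugs,proteins,diseases,bioprocesses Character vectors of
#'   explicitly registered entity identifiers (lowercase atoms).
#' @param oncogenes,suppressors Character vectors of protein identifiers
#'   asserted as oncogenes / tumor suppressors.  A protein may carry both
#'   labels; curated sources genuinely conflict.
#' @param promoting_bps,resisting_bps Character vectors of bioprocess
#'   identifiers asserted cancer-promoting / cancer-resisting.  These two
#'   sets must be disjoint.
#' @param auto_register Register identifiers referenced by facts instead
#'   of requiring explicit declaration.
#' @return A `moa_kb` object: a list of tibbles `entities`, `classes`,
#'   `interactions`, `disease_relations`, `bioprocess_relations`.
#' @examples
#' kb <- knowledge_base(
#'   interactions = data.frame(
#'     subject = "dipyridamole", verb = "inhibits", object = "ada"
#'   ),
#'   disease_relations = data.frame(
#'     protein = "ada", expression_state = "overexpressed", disease = "cancer"
#'   )
#' )
#' kb
#' @seealso [parse_fact_file()], [serialize_facts()], [infer()]
#' @export
knowledge_base <- function(interactions = NULL,
                           disease_relations = NULL,
                           bioprocess_relations = NULL,
                           drugs = character(),
                           proteins = character(),
                           diseases = character(),
                           bioprocesses = character(),
                           oncogenes = character(),
                           suppressors = character(),
                           promoting_bps = character(),
                           resisting_bps = character(),
                           auto_register = TRUE) {
  interactions <- complete_fact_table(
    interactions, c("subject", "verb", "object"),
    default_source = NA_character_, evidence = TRUE
  )
  disease_relations <- complete_fact_table(
    disease_relations, c("protein", "expression_state", "disease"),
    default_source = "text_mining", evidence = TRUE
  )
  bioprocess_relations <- complete_fact_table(
    bioprocess_relations, c("protein", "bioprocess"),
    default_source = "go", evidence = FALSE
  )

  # default interaction source depends on the subject kind, filled below
  classes <- bind_rows(
    tibble(id = as.character(oncogenes),    class = "oncogene"),
    tibble(id = as.character(suppressors),  class = "suppressor"),
    tibble(id = as.character(promoting_bps), class = "promoting_bp"),
    tibble(id = as.character(resisting_bps), class = "resisting_bp")
  )
  if (nrow(classes) == 0) {
    classes <- tibble(id = character(), class = character(), source = character())
  } else if (!"source" %in% names(classes)) {
    classes$source <- ifelse(classes$class %in% c("oncogene", "suppressor"),
                             "cancer_genes", "go")
  }

  entities <- tibble(
    id = c(as.character(drugs), as.character(proteins),
           as.character(diseases), as.character(bioprocesses)),
    type = rep(c("drug", "protein", "disease", "bioprocess"),
               times = c(length(drugs), length(proteins),
                         length(diseases), length(bioprocesses)))
  )

  if (auto_register) {
    entities <- auto_register_entities(
      entities, classes, interactions, disease_relations, bioprocess_relations
    )
  }

  # fill interaction sources now that drug/protein status is known
  drug_ids <- entities$id[entities$type == "drug"]
  missing_src <- is.na(interactions$source)
  interactions$source[missing_src] <-
    ifelse(interactions$subject[missing_src] %in% drug_ids,
           "drugbank", "text_mining")

  kb <- structure(
    list(
      entities = arrange(distinct(entities), .data$type, .data$id),
      classes = arrange(distinct(classes), .data$class, .data$id),
      interactions = dedupe_facts(interactions, c("subject", "verb", "object", "source")),
      disease_relations = dedupe_facts(
        disease_relations, c("protein", "expression_state", "disease", "source")
      ),
      bioprocess_relations = dedupe_facts(
        bioprocess_relations, c("protein", "bioprocess", "source")
      )
    ),
    class = "moa_kb"
  )
  validate_kb(kb)
  kb
}

complete_fact_table <- function(x, cols, default_source, evidence) {
  want <- c(cols, "source", if (evidence) "evidence")
  if (is.null(x) || nrow(as.data.frame(x)) == 0) {
    out <- as_tibble(stats::setNames(
      rep(list(character()), length(want)), want
    ))
    return(out)
  }
  x <- as_tibble(x)
  missing_cols <- setdiff(cols, names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf("fact table is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (!"source" %in% names(x)) x$source <- default_source
  x$source[is.na(x$source)] <- default_source
  if (evidence && !"evidence" %in% names(x)) x$evidence <- NA_character_
  x[want] <- lapply(x[want], as.character)
  x[want]
}

dedupe_facts <- function(x, key_cols) {
  # set semantics on the fact tuple; the first evidence string wins
  x <- distinct(x, dplyr::across(dplyr::all_of(key_cols)), .keep_all = TRUE)
  arrange(x, dplyr::across(dplyr::all_of(key_cols)))
}

auto_register_entities <- function(entities, classes, interactions,
                                   disease_relations, bioprocess_relations) {
  add <- function(ids, type) {
    ids <- setdiff(unique(ids), entities$id)
    if (length(ids)) {
      entities <<- bind_rows(entities, tibble(id = ids, type = type))
    }
  }
  add(classes$id[classes$class %in% c("oncogene", "suppressor")], "protein")
  add(classes$id[classes$class %in% c("promoting_bp", "resisting_bp")], "bioprocess")
  add(c(interactions$object, disease_relations$protein,
        bioprocess_relations$protein), "protein")
  # an undeclared subject never seen in a protein slot is taken to be a drug
  prot_ids <- entities$id[entities$type == "protein"]
  subj <- unique(interactions$subject)
  add(setdiff(subj, prot_ids), "drug")
  add(disease_relations$disease, "disease")
  add(bioprocess_relations$bioprocess, "bioprocess")
  entities
}

#' Validate knowledge-base invariants
#'
#' Checks the structural invariants of a [knowledge_base()]: disjoint
#' entity registries, well-formed lowercase atoms, verbs and expression
#' states drawn from their two-valued vocabularies, referential
#' integrity of every fact, no self-interactions, class assertions that
#' refer to registered proteins/bioprocesses, disjoint
#' promoting/resisting bioprocess classes, and recognised source tags.
#'
#' @param kb A `moa_kb` object.
#' @return `kb`, invisibly; aborts with all violations listed otherwise.
#' @export
validate_kb <- function(kb) {
  problems <- character()
  note <- function(...) problems <<- c(problems, sprintf(...))

  ent <- kb$entities
  bad_atoms <- unique(ent$id[!is_atom(ent$id)])
  if (length(bad_atoms)) {
    note("malformed identifier(s): %s", paste(bad_atoms, collapse = ", "))
  }
  dup <- unique(ent$id[duplicated(ent$id)])
  if (length(dup)) {
    note("identifier(s) registered in more than one class: %s",
         paste(dup, collapse = ", "))
  }
  drugs <- ent$id[ent$type == "drug"]
  prots <- ent$id[ent$type == "protein"]
  dises <- ent$id[ent$type == "disease"]
  bps   <- ent$id[ent$type == "bioprocess"]

  inter <- kb$interactions
  bad_verb <- unique(inter$verb[!inter$verb %in% c("induces", "inhibits")])
  if (length(bad_verb)) note("unknown verb(s): %s", paste(bad_verb, collapse = ", "))
  if (any(inter$subject == inter$object)) {
    note("self-interaction(s): %s",
         paste(unique(inter$subject[inter$subject == inter$object]), collapse = ", "))
  }
  unreg <- unique(c(
    setdiff(inter$subject, c(drugs, prots)),
    setdiff(inter$object, prots),
    setdiff(kb$disease_relations$protein, prots),
    setdiff(kb$disease_relations$disease, dises),
    setdiff(kb$bioprocess_relations$protein, prots),
    setdiff(kb$bioprocess_relations$bioprocess, bps)
  ))
  if (length(unreg)) {
    note("fact(s) reference unregistered identifier(s): %s",
         paste(unreg, collapse = ", "))
  }

  bad_state <- unique(kb$disease_relations$expression_state[
    !kb$disease_relations$expression_state %in% c("overexpressed", "underexpressed")
  ])
  if (length(bad_state)) {
    note("unknown expression state(s): %s", paste(bad_state, collapse = ", "))
  }

  cls <- kb$classes
  if (!all(cls$class %in% names(CLASS_PREDICATES))) {
    note("unknown class assertion kind(s): %s",
         paste(setdiff(cls$class, names(CLASS_PREDICATES)), collapse = ", "))
  }
  gene_cls <- cls$id[cls$class %in% c("oncogene", "suppressor")]
  if (length(setdiff(gene_cls, prots))) {
    note("oncogene/suppressor assertion(s) on unregistered protein(s): %s",
         paste(setdiff(gene_cls, prots), collapse = ", "))
  }
  bp_cls <- cls$id[cls$class %in% c("promoting_bp", "resisting_bp")]
  if (length(setdiff(bp_cls, bps))) {
    note("bioprocess class assertion(s) on unregistered bioprocess(es): %s",
         paste(setdiff(bp_cls, bps), collapse = ", "))
  }
  both <- intersect(cls$id[cls$class == "promoting_bp"],
                    cls$id[cls$class == "resisting_bp"])
  if (length(both)) {
    note("bioprocess(es) asserted both promoting and resisting: %s",
         paste(both, collapse = ", "))
  }

  src <- c(inter$source, kb$disease_relations$source,
           kb$bioprocess_relations$source, cls$source)
  if (length(setdiff(unique(src), SOURCE_TAGS))) {
    note("unknown source tag(s): %s",
         paste(setdiff(unique(src), SOURCE_TAGS), collapse = ", "))
  }

  if (length(problems)) {
    abort(c("invalid knowledge base", stats::setNames(problems, rep("x", length(problems)))))
  }
  invisible(kb)
}

kb_entity_ids <- function(kb, type) kb$entities$id[kb$entities$type == type]

#' Registered entity identifiers
#'
#' @param kb A `moa_kb` object.
#' @return Character vector of identifiers of the requested kind, sorted.
#' @name kb-accessors
NULL

#' @rdname kb-accessors
#' @export
kb_drugs <- function(kb) kb_entity_ids(kb, "drug")

#' @rdname kb-accessors
#' @export
kb_proteins <- function(kb) kb_entity_ids(kb, "protein")

#' @rdname kb-accessors
#' @export
kb_diseases <- function(kb) kb_entity_ids(kb, "disease")

#' @rdname kb-accessors
#' @export
kb_bioprocesses <- function(kb) kb_entity_ids(kb, "bioprocess")

kb_class_ids <- function(kb, cls) sort(kb$classes$id[kb$classes$class == cls])

#' @export
print.moa_kb <- function(x, ...) {
  cat("<moa_kb>\n")
  cat(sprintf("  entities: %d drugs, %d proteins, %d diseases, %d bioprocesses\n",
              length(kb_drugs(x)), length(kb_proteins(x)),
              length(kb_diseases(x)), length(kb_bioprocesses(x))))
  cat(sprintf("  classes: %d oncogenes, %d suppressors, %d promoting bps, %d resisting bps\n",
              length(kb_class_ids(x, "oncogene")),
              length(kb_class_ids(x, "suppressor")),
              length(kb_class_ids(x, "promoting_bp")),
              length(kb_class_ids(x, "resisting_bp"))))
  drug_ids <- kb_drugs(x)
  n_dt <- sum(x$interactions$subject %in% drug_ids)
  cat(sprintf("  facts: %d drug-target, %d protein-protein, %d gene-disease, %d gene-bioprocess\n",
              n_dt, nrow(x$interactions) - n_dt,
              nrow(x$disease_relations), nrow(x$bioprocess_relations)))
  invisible(x)
}

#' Restrict a knowledge base to provenance sources
#'
#' Retains the full entity registry and every drug-target interaction
#' (a chain cannot start without an initial drug edge), and keeps the
#' remaining knowledge — protein-protein interactions, gene-disease
#' relations, gene-bioprocess relations and class assertions — only when
#' its provenance tag is in `sources`.  This is the per-column operation
#' behind [source_ablation()].
#'
#' @param kb A `moa_kb` object.
#' @param sources Character vector of source tags to retain.
#' @return A filtered `moa_kb`.
#' @export
filter_kb_sources <- function(kb, sources) {
  bad <- setdiff(sources, SOURCE_TAGS)
  if (length(bad)) {
    abort(sprintf("unknown source tag(s): %s", paste(bad, collapse = ", ")))
  }
  drug_ids <- kb_drugs(kb)
  out <- kb
  out$interactions <- filter(
    kb$interactions,
    .data$subject %in% drug_ids | .data$source %in% sources
  )
  out$disease_relations <- filter(kb$disease_relations, .data$source %in% sources)
  out$bioprocess_relations <- filter(kb$bioprocess_relations, .data$source %in% sources)
  out$classes <- filter(kb$classes, .data$source %in% sources)
  out
}
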