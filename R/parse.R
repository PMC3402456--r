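#' Parse the logic-fact dialect into a knowledge base
#'
#' Reads ground facts in the answer-set-programming surface syntax used
#' for knowledge exchange: one or more statements of the form
#' `predicate(arg, arg, ...).` per line, lowercase atoms, at most one
#' level of nested functional terms (`overexpressed(ada)`), `%` starting
#' a comment, blank lines allowed.  Recognised predicates are the entity
#' registrations (`drug/1`, `protein/1`, `disease/1`, `bioprocess/1`),
#' the class assertions (`oncogene/1`, `suppressor/1`,
#' `cancer_promoting_bioprocess/1`, `cancer_resisting_bioprocess/1`),
#' `interaction/3` and `relation/3`.  Class assertions register their
#' entity; `interaction` and `relation` facts must reference registered
#' identifiers (declaration order within the file does not matter).
#'
#' Provenance tags are not part of the surface syntax; parsed facts get
#' source defaults by kind: drug-subject interactions `drugbank`,
#' protein-protein interactions and gene-disease relations
#' `text_mining`, bioprocess facts `go`, oncogene/suppressor assertions
#' `cancer_genes`.
#'
#' @param text A character scalar (or vector of lines) of fact text.
#' @return A [knowledge_base()] containing exactly the parsed facts.
#' @examples
#' kb <- parse_fact_file("
#'   drug(dipyridamole). protein(ada). disease(cancer).
#'   interaction(dipyridamole, inhibits, ada).
#'   relation(overexpressed(ada), associated_with, cancer).
#' ")
#' kb
#' @export
parse_fact_file <- function(text) {
  lines <- unlist(str_split(paste(text, collapse = "\n"), "\n"))
  acc <- list(
    entities = list(), classes = list(),
    interactions = list(), disease_relations = list(),
    bioprocess_relations = list()
  )
  for (i in seq_along(lines)) {
    line <- sub("%.*$", "", lines[[i]])
    if (!nzchar(str_trim(line))) next
    for (stmt in split_statements(line, i)) {
      acc <- parse_statement(stmt, i, acc)
    }
  }
  ent <- bind_rows(acc$entities)
  cls <- bind_rows(acc$classes)
  if (nrow(ent) == 0) ent <- tibble(id = character(), type = character())
  if (nrow(cls) == 0) cls <- tibble(id = character(), class = character())

  kb <- knowledge_base(
    interactions = if (length(acc$interactions)) bind_rows(acc$interactions),
    disease_relations = if (length(acc$disease_relations)) bind_rows(acc$disease_relations),
    bioprocess_relations = if (length(acc$bioprocess_relations)) bind_rows(acc$bioprocess_relations),
    drugs = ent$id[ent$type == "drug"],
    proteins = unique(c(ent$id[ent$type == "protein"],
                        cls$id[cls$class %in% c("oncogene", "suppressor")])),
    diseases = ent$id[ent$type == "disease"],
    bioprocesses = unique(c(ent$id[ent$type == "bioprocess"],
                            cls$id[cls$class %in% c("promoting_bp", "resisting_bp")])),
    oncogenes = cls$id[cls$class == "oncogene"],
    suppressors = cls$id[cls$class == "suppressor"],
    promoting_bps = cls$id[cls$class == "promoting_bp"],
    resisting_bps = cls$id[cls$class == "resisting_bp"],
    auto_register = FALSE
  )
  kb
}

#' Read a knowledge base from a fact file
#'
#' @param path Path to a `.lp` fact file.
#' @return A `moa_kb` object.
#' @export
read_kb <- function(path) {
  parse_fact_file(readLines(path, warn = FALSE))
}

# split a physical line into `pred(...)` statements at top-level periods
split_statements <- function(line, lineno) {
  chars <- strsplit(line, "", fixed = TRUE)[[1]]
  depth <- 0L
  buf <- character()
  out <- character()
  for (ch in chars) {
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (depth < 0L) {
      abort(sprintf("syntax error on line %d: unbalanced parentheses", lineno))
    }
    if (ch == "." && depth == 0L) {
      stmt <- str_trim(paste(buf, collapse = ""))
      if (!nzchar(stmt)) {
        abort(sprintf("syntax error on line %d: empty statement", lineno))
      }
      out <- c(out, stmt)
      buf <- character()
    } else {
      buf <- c(buf, ch)
    }
  }
  if (depth != 0L || nzchar(str_trim(paste(buf, collapse = "")))) {
    abort(sprintf(
      "syntax error on line %d: statement not terminated by '.'", lineno
    ))
  }
  out
}

split_args <- function(argstr, lineno) {
  chars <- strsplit(argstr, "", fixed = TRUE)[[1]]
  depth <- 0L
  buf <- character()
  out <- character()
  for (ch in chars) {
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (ch == "," && depth == 0L) {
      out <- c(out, str_trim(paste(buf, collapse = "")))
      buf <- character()
    } else {
      buf <- c(buf, ch)
    }
  }
  c(out, str_trim(paste(buf, collapse = "")))
}

parse_statement <- function(stmt, lineno, acc) {
  m <- regmatches(stmt, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\((.*)\\)$", stmt))[[1]]
  if (length(m) != 3) {
    abort(sprintf("syntax error on line %d: malformed term '%s'", lineno, stmt))
  }
  pred <- m[[2]]
  args <- split_args(m[[3]], lineno)
  need_atom <- function(a) {
    if (!is_atom(a)) {
      abort(sprintf("syntax error on line %d: malformed atom '%s'", lineno, a))
    }
    a
  }
  arity <- function(n) {
    if (length(args) != n) {
      abort(sprintf("syntax error on line %d: %s/%d expects %d argument(s)",
                    lineno, pred, length(args), n))
    }
  }

  if (pred %in% ENTITY_PREDICATES) {
    arity(1)
    type <- names(ENTITY_PREDICATES)[match(pred, ENTITY_PREDICATES)]
    acc$entities <- c(acc$entities, list(tibble(id = need_atom(args[[1]]), type = type)))
  } else if (pred %in% CLASS_PREDICATES) {
    arity(1)
    cls <- names(CLASS_PREDICATES)[match(pred, CLASS_PREDICATES)]
    acc$classes <- c(acc$classes, list(tibble(id = need_atom(args[[1]]), class = cls)))
  } else if (pred == "interaction") {
    arity(3)
    verb <- need_atom(args[[2]])
    if (!verb %in% c("induces", "inhibits")) {
      abort(sprintf("syntax error on line %d: unknown interaction verb '%s'",
                    lineno, verb))
    }
    acc$interactions <- c(acc$interactions, list(tibble(
      subject = need_atom(args[[1]]), verb = verb, object = need_atom(args[[3]])
    )))
  } else if (pred == "relation") {
    arity(3)
    verb <- args[[2]]
    if (verb == "associated_with") {
      mm <- regmatches(
        args[[1]],
        regexec("^(overexpressed|underexpressed)\\(([a-z][a-z0-9_]*)\\)$", args[[1]])
      )[[1]]
      if (length(mm) != 3) {
        abort(sprintf(
          "syntax error on line %d: associated_with needs an expression-state term, got '%s'",
          lineno, args[[1]]
        ))
      }
      acc$disease_relations <- c(acc$disease_relations, list(tibble(
        protein = mm[[3]], expression_state = mm[[2]],
        disease = need_atom(args[[3]])
      )))
    } else if (verb == "is_associated") {
      acc$bioprocess_relations <- c(acc$bioprocess_relations, list(tibble(
        protein = need_atom(args[[1]]), bioprocess = need_atom(args[[3]])
      )))
    } else {
      abort(sprintf("syntax error on line %d: unknown relation verb '%s'",
                    lineno, verb))
    }
  } else {
    abort(sprintf("unknown predicate '%s' on line %d", pred, lineno))
  }
  acc
}
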