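test_that("parsing the canonical direct-inference facts yields the expected KB", {
  kb <- parse_fact_file(
    "drug(dipyridamole). protein(ada). disease(cancer).
     interaction(dipyridamole, inhibits, ada).
     relation(overexpressed(ada), associated_with, cancer)."
  )
  expect_identical(kb_drugs(kb), "dipyridamole")
  expect_identical(kb_proteins(kb), "ada")
  expect_identical(kb_diseases(kb), "cancer")
  expect_equal(nrow(kb$interactions), 1L)
  expect_equal(nrow(kb$disease_relations), 1L)
  expect_identical(kb$interactions$verb, "inhibits")
  expect_identical(kb$disease_relations$expression_state, "overexpressed")
  # kind-based default provenance
  expect_identical(kb$interactions$source, "drugbank")
  expect_identical(kb$disease_relations$source, "text_mining")
})

test_that("empty input parses to an empty KB and serializes to empty text", {
  kb <- parse_fact_file("")
  expect_equal(nrow(kb$entities), 0L)
  expect_equal(nrow(kb$interactions), 0L)
  expect_identical(serialize_facts(kb), "")
})

test_that("comments, blank lines and declaration order are tolerated", {
  kb <- parse_fact_file("
    % the relation precedes the declarations
    interaction(egf, induces, erbb2).  % trailing comment

    protein(egf). protein(erbb2).
  ")
  expect_equal(nrow(kb$interactions), 1L)
  # a protein-protein interaction defaults to text-mined provenance
  expect_identical(kb$interactions$source, "text_mining")
})

test_that("malformed input is rejected with the offending line number", {
  expect_error(parse_fact_file("protein(ada)"), "line 1")
  expect_error(parse_fact_file("protein(ada).\nfoo bar."), "line 2")
  expect_error(parse_fact_file("relation(ada, associated_with, cancer)."),
               "expression-state")
  expect_error(parse_fact_file("protein(Ada)."), "malformed atom")
  expect_error(parse_fact_file("interaction(a, blocks, b)."), "verb")
  expect_error(parse_fact_file("frobnicates(ada)."), "unknown predicate")
  expect_error(parse_fact_file("protein(a). protein(b). interaction(a, induces, b, c)."),
               "3 argument")
})

test_that("facts referencing unregistered identifiers are rejected by name", {
  expect_error(
    parse_fact_file("drug(dipyridamole). interaction(dipyridamole, inhibits, ada)."),
    "ada"
  )
  expect_error(
    parse_fact_file("protein(ada). relation(overexpressed(ada), associated_with, cancer)."),
    "cancer"
  )
})

test_that("class assertions register their entity; mixed classes are allowed", {
  kb <- parse_fact_file("oncogene(egfr). suppressor(egfr).
                         cancer_promoting_bioprocess(pos_reg_cell_proliferation).")
  expect_identical(kb_proteins(kb), "egfr")
  expect_identical(kb_bioprocesses(kb), "pos_reg_cell_proliferation")
  expect_setequal(kb$classes$class[kb$classes$id == "egfr"],
                  c("oncogene", "suppressor"))
  # but a bioprocess cannot be both promoting and resisting
  expect_error(
    parse_fact_file("cancer_promoting_bioprocess(x). cancer_resisting_bioprocess(x)."),
    "both promoting and resisting"
  )
})

test_that("serialization is deterministic, sorted, and emits fact-dialect lines", {
  kb <- knowledge_base(
    interactions = data.frame(subject = "egf", verb = "induces",
                              object = "erbb2"),
    proteins = c("erbb2", "egf")
  )
  txt <- serialize_facts(kb)
  expect_match(txt, "interaction\\(egf, induces, erbb2\\)\\.", fixed = FALSE)
  lines <- strsplit(txt, "\n")[[1]]
  expect_identical(lines, sort(lines, method = "radix"))
  expect_identical(serialize_facts(kb), txt)
})

test_that("parse/serialize round-trips generator output", {
  for (seed in 1:25) {
    g <- generate_kb(small_synth_params(seed, planted_depth = 2L + seed %% 3))
    txt <- serialize_facts(g$kb)
    kb2 <- parse_fact_file(txt)
    expect_identical(serialize_facts(kb2), txt)
    # full structural equality modulo evidence (not representable in the dialect)
    expect_identical(kb2$entities, g$kb$entities)
    expect_identical(kb2$classes, g$kb$classes)
    expect_identical(dplyr::select(kb2$interactions, -evidence),
                     dplyr::select(g$kb$interactions, -evidence))
    expect_identical(dplyr::select(kb2$disease_relations, -evidence),
                     dplyr::select(g$kb$disease_relations, -evidence))
    expect_identical(kb2$bioprocess_relations, g$kb$bioprocess_relations)
  }
})

test_that("duplicate facts collapse to set semantics", {
  kb <- knowledge_base(
    interactions = data.frame(
      subject = c("d", "d"), verb = c("inhibits", "inhibits"),
      object = c("p", "p"), evidence = c("PMID:1", "PMID:2")
    )
  )
  expect_equal(nrow(kb$interactions), 1L)
  expect_error(
    knowledge_base(interactions = data.frame(
      subject = "p", verb = "induces", object = "p"
    ), proteins = "p", auto_register = FALSE),
    "self-interaction"
  )
})

test_that("drug-target loader maps pharmacological actions and normalizes ids", {
  out <- load_drug_target_table(data.frame(
    drug = c("Dipyridamole", "Tazarotene"),
    target = c("ADA", "RARA"),
    action = c("antagonist", "agonist")
  ))
  expect_identical(out$subject, c("dipyridamole", "tazarotene"))
  expect_identical(out$verb, c("inhibits", "induces"))
  expect_identical(out$object, c("ada", "rara"))
  expect_identical(unique(out$source), "drugbank")

  expect_equal(nrow(load_drug_target_table(data.frame(
    drug = character(), target = character(), action = character()
  ))), 0L)

  expect_warning(
    out2 <- load_drug_target_table(data.frame(
      drug = c("a", "b"), target = c("x", "y"),
      action = c("antagonist", "modulator")
    )),
    "modulator"
  )
  expect_equal(nrow(out2), 1L)
  expect_equal(nrow(attr(out2, "rejected")), 1L)

  expect_message(
    out3 <- load_drug_target_table(data.frame(
      drug = c("a", "a"), target = c("x", "x"),
      action = c("antagonist", "antagonist")
    )),
    "duplicate"
  )
  expect_equal(nrow(out3), 1L)
})

test_that("relation loader routes triples by verb and enforces qualifiers", {
  out <- load_relation_table(data.frame(
    subject = c("AMACR", "TNF", "PNP"),
    verb = c("associated_with", "inhibits", "is_associated"),
    object = c("gastric cancer", "PPARG", "pos reg cell proliferation"),
    qualifier = c("overexpressed", "-", NA)
  ))
  expect_identical(out$disease_relations$protein, "amacr")
  expect_identical(out$disease_relations$disease, "gastric_cancer")
  expect_identical(out$interactions$subject, "tnf")
  expect_identical(out$interactions$verb, "inhibits")
  expect_identical(out$bioprocess_relations$bioprocess,
                   "pos_reg_cell_proliferation")

  empty <- load_relation_table(data.frame(
    subject = character(), verb = character(), object = character()
  ))
  expect_equal(nrow(empty$interactions), 0L)
  expect_equal(nrow(empty$disease_relations), 0L)
  expect_equal(nrow(empty$bioprocess_relations), 0L)

  expect_error(load_relation_table(data.frame(
    subject = "a", verb = "associated_with", object = "cancer", qualifier = NA
  )), "qualifier")
  expect_error(load_relation_table(data.frame(
    subject = "a", verb = "correlates", object = "b", qualifier = NA
  )), "unknown verb")
})

test_that("loader output is order-independent as a fact set", {
  rows <- data.frame(
    drug = c("a", "b", "c"), target = c("x", "y", "z"),
    action = c("agonist", "antagonist", "agonist")
  )
  fwd <- load_drug_target_table(rows)
  rev <- load_drug_target_table(rows[3:1, ])
  key <- function(d) sort(paste(d$subject, d$verb, d$object))
  expect_identical(key(fwd), key(rev))
})

test_that("disease-class mapping follows members, then patterns, idempotently", {
  m <- disease_class_map()
  expect_identical(map_disease_class("gastric_cancer", m), "cancer")
  expect_identical(map_disease_class("acute_lymphoblastic_leukemia", m), "cancer")
  expect_identical(map_disease_class("depression", m), NA_character_)
  # explicit membership beats (absent) pattern matches
  m2 <- disease_class_map(members = "depression", patterns = character())
  expect_identical(map_disease_class("depression", m2), "cancer")
  expect_identical(map_disease_class("gastric_cancer", m2), NA_character_)
  # vectorized, order-independent, idempotent for a fixed pattern list
  ds <- c("melanoma", "asthma", "t_cell_lymphoma")
  expect_identical(map_disease_class(ds, m), c("cancer", NA, "cancer"))
  expect_identical(map_disease_class(rev(ds), m), rev(map_disease_class(ds, m)))
})

test_that("disease-map config round-trips through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("target_class: cancer", "members: [weird_syndrome]",
               "patterns: [oma]"), path)
  m <- read_disease_map(path)
  expect_identical(map_disease_class("weird_syndrome", m), "cancer")
  expect_identical(map_disease_class("melanoma", m), "cancer")
  expect_identical(map_disease_class("cancer", m), NA_character_)
})

test_that("the canonical bioprocess classes build a valid knowledge base", {
  bp <- cancer_bioprocess_classes()
  kb <- knowledge_base(
    bioprocess_relations = data.frame(protein = "pnp",
                                      bioprocess = "pos_reg_cell_proliferation"),
    promoting_bps = bp$bioprocess[bp$class == "promoting_bp"],
    resisting_bps = bp$bioprocess[bp$class == "resisting_bp"]
  )
  expect_identical(sort(kb_bioprocesses(kb)), sort(bp$bioprocess))
  # and they drive the anti-mechanism rules
  kb2 <- knowledge_base(
    interactions = data.frame(subject = "cladribine", verb = "induces",
                              object = "pnp"),
    bioprocess_relations = data.frame(protein = "pnp",
                                      bioprocess = "pos_reg_cell_proliferation"),
    promoting_bps = bp$bioprocess[bp$class == "promoting_bp"],
    resisting_bps = bp$bioprocess[bp$class == "resisting_bp"]
  )
  expect_identical(infer(kb2, "cladribine")$report$verdict, "promoting_only")
})

test_that("identifier normalization produces lowercase atoms", {
  expect_identical(normalize_atom(c("Dipyridamole", "RAR-alpha", " TP53 ")),
                   c("dipyridamole", "rar_alpha", "tp53"))
  expect_identical(normalize_atom("positive regulation of cell proliferation"),
                   "positive_regulation_of_cell_proliferation")
})
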