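test_that("initial triggers follow the drug-target edge sign", {
  kb <- example_kb("dipyridamole")
  t1 <- initial_triggers(kb, "dipyridamole")
  expect_equal(nrow(t1), 1L)
  expect_identical(t1$action, "inactivates")
  expect_identical(t1$target, "ada")
  expect_identical(t1$step, 1L)
  expect_identical(t1$rule, "R1a")

  t2 <- initial_triggers(example_kb("tazarotene"), "tazarotene")
  expect_identical(t2$action, "activates")
  expect_identical(t2$target, "rara")
  expect_identical(t2$rule, "R1b")

  kb3 <- knowledge_base(drugs = "lonely", auto_register = FALSE)
  expect_equal(nrow(initial_triggers(kb3, "lonely")), 0L)
  expect_error(initial_triggers(kb3, "ghost"), "ghost")
})

test_that("propagation applies the signed transition table and policy gates", {
  kb <- example_kb("tazarotene")
  t1 <- initial_triggers(kb, "tazarotene")
  nxt <- propagate(kb, t1)
  expect_equal(nrow(nxt), 1L)
  expect_identical(nxt$action, "inactivates")
  expect_identical(nxt$target, "egfr")
  expect_identical(nxt$step, 2L)
  expect_identical(nxt$rule, "R2b")

  # no outgoing edges -> nothing fires
  expect_equal(nrow(propagate(kb, nxt)), 0L)

  # R2c (loss of activator) is gated by inactivation_propagation
  kb2 <- knowledge_base(
    interactions = data.frame(subject = c("d", "p1"),
                              verb = c("inhibits", "induces"),
                              object = c("p1", "p2"))
  )
  t <- initial_triggers(kb2, "d")
  on <- propagate(kb2, t, engine_policy())
  expect_identical(on$rule, "R2c")
  expect_identical(on$action, "inactivates")
  off <- propagate(kb2, t, engine_policy(inactivation_propagation = FALSE))
  expect_equal(nrow(off), 0L)

  # R2d (double negation) is off by default
  kb3 <- knowledge_base(
    interactions = data.frame(subject = c("d", "p1"),
                              verb = c("inhibits", "inhibits"),
                              object = c("p1", "p2"))
  )
  t3 <- initial_triggers(kb3, "d")
  expect_equal(nrow(propagate(kb3, t3)), 0L)
  dn <- propagate(kb3, t3, engine_policy(double_negation_rule = TRUE))
  expect_identical(dn$rule, "R2d")
  expect_identical(dn$action, "activates")
})

test_that("terminal rules fire once per (rule, supporting fact)", {
  kb <- example_kb("dipyridamole")
  t1 <- initial_triggers(kb, "dipyridamole")
  term <- terminal_triggers(kb, t1)
  expect_equal(nrow(term), 1L)
  expect_identical(term$action, "treats")
  expect_identical(term$target, "cancer")
  expect_identical(term$step, 2L)
  expect_identical(term$rule, "R3a")

  kb2 <- example_kb("tazarotene")
  t2 <- propagate(kb2, initial_triggers(kb2, "tazarotene"))
  term2 <- terminal_triggers(kb2, t2)
  expect_identical(term2$rule, "R4")
  expect_identical(term2$step, 3L)

  # activating an oncogene is no treats condition
  kb3 <- knowledge_base(
    interactions = data.frame(subject = "d", verb = "induces", object = "p"),
    oncogenes = "p"
  )
  expect_equal(nrow(terminal_triggers(kb3, initial_triggers(kb3, "d"))), 0L)
})

test_that("anti-mechanism rules mirror the terminal rules", {
  kb <- example_kb("cladribine")
  t1 <- initial_triggers(kb, "cladribine")
  con <- contradiction_triggers(kb, t1)
  expect_equal(nrow(con), 1L)
  expect_identical(con$action, "promotes")
  expect_identical(con$rule, "C3")
  expect_identical(con$step, 2L)

  kb2 <- knowledge_base(
    interactions = data.frame(subject = "d", verb = "induces", object = "p")
  )
  expect_equal(nrow(contradiction_triggers(kb2, initial_triggers(kb2, "d"))), 0L)
})

test_that("the direct worked example yields exactly one 2-step direct chain", {
  fit <- infer(example_kb("dipyridamole"), "dipyridamole")
  expect_equal(nrow(fit$chain_info), 1L)
  expect_identical(fit$chain_info$classification, "direct")
  ch <- fit$chains
  expect_identical(ch$action, c("inactivates", "treats"))
  expect_identical(ch$target, c("ada", "cancer"))
  expect_identical(ch$step, c(1L, 2L))
  expect_identical(fit$report$verdict, "clean")
})

test_that("the indirect worked example yields exactly one 3-step indirect chain", {
  fit <- infer(example_kb("tazarotene"), "tazarotene")
  expect_equal(nrow(fit$chain_info), 1L)
  expect_identical(fit$chain_info$classification, "indirect")
  ch <- fit$chains
  expect_identical(ch$action, c("activates", "inactivates", "treats"))
  expect_identical(ch$target, c("rara", "egfr", "cancer"))
  expect_identical(ch$step, 1:3)
  expect_identical(ch$rule, c("R1b", "R2b", "R4"))
})

test_that("distinct supporting facts yield distinct chains, deduplicated and ordered", {
  # two in-class disease relations on the same protein -> two R3a chains
  kb <- knowledge_base(
    interactions = data.frame(subject = "d", verb = "inhibits", object = "p"),
    disease_relations = data.frame(
      protein = "p", expression_state = "overexpressed",
      disease = c("gastric_cancer", "melanoma")
    )
  )
  fit <- infer(kb, "d")
  expect_equal(nrow(fit$chain_info), 2L)
  expect_identical(fit$chain_info$classification, c("direct", "direct"))
  keys <- chain_keys(fit$chains)
  expect_equal(length(unique(keys)), 2L)
  # re-running returns the identical ordering
  expect_identical(chain_keys(infer(kb, "d")$chains), keys)
})

test_that("chains never revisit a protein and respect max_depth", {
  # 3-cycle: a induces b induces c induces a; c is an oncogene
  kb <- knowledge_base(
    interactions = data.frame(
      subject = c("d", "a", "b", "c"),
      verb = "induces",
      object = c("a", "b", "c", "a")
    ),
    suppressors = "c"
  )
  fit <- infer(kb, "d", policy = engine_policy(max_depth = 5))
  expect_equal(nrow(fit$chain_info), 1L)
  steps <- fit$chains
  expect_identical(steps$target, c("a", "b", "c", "cancer"))
  expect_false(anyDuplicated(steps$target[-nrow(steps)]) > 0)

  # a linear chain longer than max_depth is cut off
  kb2 <- knowledge_base(
    interactions = data.frame(
      subject = c("d", "p1", "p2", "p3", "p4"),
      verb = "induces",
      object = c("p1", "p2", "p3", "p4", "p5")
    ),
    suppressors = "p5"
  )
  expect_equal(nrow(infer(kb2, "d", policy = engine_policy(max_depth = 3))$chain_info), 0L)
  deep <- infer(kb2, "d", policy = engine_policy(max_depth = 5))
  expect_equal(nrow(deep$chain_info), 1L)
  expect_equal(max(deep$chains$step), 6L)
  expect_error(engine_policy(max_depth = 1), "max_depth")
})

test_that("contradiction modes block, flag and ignore behave as documented", {
  # d inhibits p (oncogene -> treats via R4) and d induces q (oncogene -> C1)
  kb <- knowledge_base(
    interactions = data.frame(subject = c("d", "d"),
                              verb = c("inhibits", "induces"),
                              object = c("p", "q")),
    oncogenes = c("p", "q")
  )
  blocked <- infer(kb, "d", policy = engine_policy(contradiction_mode = "block"))
  expect_identical(blocked$report$verdict, "contradictory")
  expect_equal(nrow(blocked$chain_info), 0L)
  expect_true(blocked$blocked)
  expect_equal(nrow(blocked$report$treating_info), 1L)

  flagged <- infer(kb, "d", policy = engine_policy(contradiction_mode = "flag"))
  expect_identical(flagged$report$verdict, "contradictory")
  expect_equal(nrow(flagged$chain_info), 1L)

  ignored <- infer(kb, "d", policy = engine_policy(contradiction_mode = "ignore"))
  expect_equal(nrow(ignored$chain_info), 1L)
  expect_equal(nrow(ignored$report$promoting_info), 0L)
  expect_identical(ignored$report$verdict, "clean")
})

test_that("drugs inferred under block are a subset of those under ignore", {
  for (seed in 1:12) {
    g <- generate_kb(small_synth_params(seed))
    blocked <- inferred_drugs(infer_all(
      g$kb, policy = engine_policy(contradiction_mode = "block")
    ))
    ignored <- inferred_drugs(infer_all(
      g$kb, policy = engine_policy(contradiction_mode = "ignore")
    ))
    expect_true(all(blocked %in% ignored))
  }
})

test_that("adding facts never removes a chain in ignore mode", {
  pol <- engine_policy(contradiction_mode = "ignore")
  for (seed in 1:8) {
    g <- generate_kb(small_synth_params(seed))
    kb_full <- g$kb
    kb_less <- kb_full
    # drop one protein-protein edge
    ppi <- which(!kb_less$interactions$subject %in% kb_drugs(kb_less))
    if (length(ppi) == 0) next
    kb_less$interactions <- kb_less$interactions[-ppi[1], ]
    for (d in kb_drugs(kb_full)) {
      less_keys <- chain_keys(infer(kb_less, d, policy = pol)$chains)
      full_keys <- chain_keys(infer(kb_full, d, policy = pol)$chains)
      expect_true(all(less_keys %in% full_keys))
    }
  }
})

test_that("anti-mechanism derivations mirror treats derivations under sign inversion", {
  # fully sign-symmetric propagation makes the mirror exact at every depth
  pol <- engine_policy(contradiction_mode = "flag",
                       double_negation_rule = TRUE,
                       inactivation_propagation = TRUE)
  mirror <- c(C1 = "R4", C2 = "R5", C3 = "R6", C4 = "R7",
              C5a = "R3a", C5b = "R3b")
  shape <- function(chains, info) {
    # step/target skeleton of each chain (rule ids differ under the mirror)
    vapply(split(seq_len(nrow(chains)), chains$chain), function(idx) {
      paste(sprintf("%d:%s", chains$step[idx], chains$target[idx]),
            collapse = "|")
    }, character(1))
  }
  for (seed in 1:10) {
    g <- generate_kb(small_synth_params(seed, planted_depth = 3L))
    flipped <- flip_drug_edges(g$kb)
    for (d in kb_drugs(g$kb)) {
      orig <- infer(g$kb, d, policy = pol)
      flip <- infer(flipped, d, policy = pol)
      expect_setequal(unname(shape(orig$report$promoting)),
                      unname(shape(flip$report$treating)))
      expect_setequal(unname(shape(orig$report$treating)),
                      unname(shape(flip$report$promoting)))
    }
  }
  # and at depth 2 the mirror holds under the default policy too
  kb <- example_kb("cladribine")
  con <- infer(kb, "cladribine", policy = engine_policy(contradiction_mode = "flag"))
  tre <- infer(flip_drug_edges(kb), "cladribine")
  expect_equal(nrow(con$report$promoting_info), nrow(tre$chain_info))
  expect_identical(tre$chain_info$terminal_rule, "R6")
  expect_identical(con$report$promoting_info$terminal_rule, "C3")
})

test_that("every returned chain re-validates against the knowledge base", {
  for (seed in 1:6) {
    g <- generate_kb(small_synth_params(seed, planted_depth = 3L))
    pol <- policy_from_grid(seed)
    for (d in kb_drugs(g$kb)) {
      fit <- infer(g$kb, d, policy = pol)
      if (nrow(fit$chains) == 0) next
      res <- validate_chains(g$kb, fit$chains, policy = pol)
      expect_true(all(res$valid))
    }
  }
})

test_that("tampered chains fail the soundness validator", {
  fit <- infer(example_kb("tazarotene"), "tazarotene")
  good <- validate_chains(example_kb("tazarotene"), fit$chains)
  expect_true(all(good$valid))

  wrong_target <- fit$chains
  wrong_target$target[2] <- "rara"
  expect_false(any(validate_chains(example_kb("tazarotene"), wrong_target)$valid))

  wrong_rule <- fit$chains
  wrong_rule$rule[3] <- "R5"
  expect_false(any(validate_chains(example_kb("tazarotene"), wrong_rule)$valid))

  gap_steps <- fit$chains
  gap_steps$step[3] <- 4L
  expect_false(any(validate_chains(example_kb("tazarotene"), gap_steps)$valid))
})

test_that("infer_all is deterministic and covers both scenario drugs", {
  kb <- example_kb("scenarios")
  screen <- infer_all(kb)
  expect_identical(screen$summary$drug, c("dipyridamole", "tazarotene"))
  expect_true(all(screen$summary$n_chains >= 1))
  expect_identical(glance(screen)$n_inferred, 2L)
  expect_identical(tidy(screen), tidy(infer_all(kb)))

  empty <- infer_all(knowledge_base())
  expect_equal(nrow(empty$summary), 0L)
  expect_equal(length(inferred_drugs(empty)), 0L)
})
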