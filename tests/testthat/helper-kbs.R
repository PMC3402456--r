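# Shared fixtures and small utilities for the suite.  Everything is
# built in code; no data files.

# the 12 policy combinations the engine admits
policy_grid <- local({
  g <- expand.grid(
    mode = c("block", "flag", "ignore"),
    dnr = c(FALSE, TRUE),
    ip = c(TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  g
})

policy_from_grid <- function(i, max_depth = 4L) {
  row <- policy_grid[((i - 1L) %% nrow(policy_grid)) + 1L, ]
  engine_policy(
    max_depth = max_depth,
    contradiction_mode = row$mode,
    double_negation_rule = row$dnr,
    inactivation_propagation = row$ip
  )
}

# dense little KBs that exercise every rule family
small_synth_params <- function(seed, planted_depth = 2L, n_proteins = 12L) {
  synth_params(
    n_drugs = 3L, n_proteins = n_proteins, n_bioprocesses = 4L,
    p_drug_edge = 0.15, p_ppi = 0.12,
    frac_oncogene = 0.15, frac_suppressor = 0.15,
    frac_disease_rel = 0.3, frac_bp_rel = 0.3,
    n_planted_chains = 1L, planted_depth = planted_depth,
    seed = seed
  )
}

# flip the sign of every drug-target edge, leaving the rest untouched
flip_drug_edges <- function(kb) {
  drug_ids <- kb_drugs(kb)
  is_dt <- kb$interactions$subject %in% drug_ids
  kb$interactions$verb[is_dt] <-
    ifelse(kb$interactions$verb[is_dt] == "induces", "inhibits", "induces")
  validate_kb(kb)
  kb
}

expect_same_chain_set <- function(a, b) {
  expect_identical(chain_keys(a), chain_keys(b))
}
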