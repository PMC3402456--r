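# drugmoa

Mechanism-of-action reasoning for drug repurposing.

`drugmoa` asks a simple question of a molecular knowledge base: *can an
existing drug be expected to treat a disease class it was never
indicated for, given only its targets and the signed interaction
network around them?*  It answers by forward chaining over typed logic
facts — drug–target edges, directed protein–protein interactions with
an `induces`/`inhibits` sign, expression-state-qualified gene–disease
associations, oncogene/tumor-suppressor assertions, and membership of
genes in cancer-promoting or cancer-resisting biological processes —
and returns explicit, auditable inference chains rather than a
co-occurrence network to sift through by eye.

## The model

Every inference step is a trigger `trigger(Dr, Action, Prot, Step)`.
Chains are built from seven mechanism rules plus their anti-mechanism
mirrors:

1. **Initial step (R1).** An antagonist edge
   `interaction(Dr, inhibits, P)` triggers `inactivates(P)` at step 1;
   an agonist edge triggers `activates(P)`.
2. **Propagation (R2).** An activated protein passes activation
   through `induces` edges and inactivation through `inhibits` edges.
   Loss-of-activator propagation (an inactivated protein that normally
   induces a partner leaves the partner inactivated) is on by default;
   the double-negation reading (inhibiting an inhibitor activates) is
   off by default.
3. **Terminal conditions (R3–R7).** `treats(cancer)` is concluded when
   the chain inactivates a protein whose *over*-expression is
   associated with a disease in the class (R3a) — or activates one
   whose *under*-expression is (R3b) — inactivates an oncogene (R4),
   activates a tumor suppressor (R5), inactivates a member of a
   cancer-promoting bioprocess (R6), or activates a member of a
   cancer-resisting one (R7).
4. **Contradictions (C1–C5).** The sign mirrors of R3–R7 derive
   `promotes(cancer)`; a drug with both derivations is contradictory
   and is, by default policy, blocked from reporting treats chains.

A chain of 2 triggers is a **direct** inference (the conclusion comes
straight from a drug target); 3 or more is **indirect**.  Chains never
revisit a protein and are bounded by a configurable step depth
(default 5).

## A worked example

```r
library(drugmoa)

kb <- parse_fact_file("
  drug(tazarotene). protein(rara). protein(egfr).
  interaction(tazarotene, induces, rara).
  interaction(rara, inhibits, egfr).
  oncogene(egfr).
")
fit <- infer(kb, "tazarotene", disease_class = "cancer")
fit
#> <moa_inference> tazarotene -> cancer: 1 chain(s), verdict clean
#>   [indirect] activates(rara)@1 -> inactivates(egfr)@2 -> treats(cancer)@3
tidy(fit)[, c("step", "action", "target", "rule")]
#> # A tibble: 3 × 4
#>    step action      target rule 
#>   <int> <chr>       <chr>  <chr>
#> 1     1 activates   rara   R1b  
#> 2     2 inactivates egfr   R2b  
#> 3     3 treats      cancer R4
```

Reading the chain: the agonist tazarotene activates its target RARA
(step 1, rule R1b); activated RARA inhibits EGFR, so EGFR is triggered
inactivated (step 2, rule R2b); EGFR is an oncogene, so its
inactivation concludes `treats(cancer)` at step 3 (rule R4) — an
indirect inference, because the anti-cancer conclusion runs through a
protein that is not itself a target of the drug.

The same API scales to screens (`infer_all()`), recall evaluation
against labeled drug sets (`label_sets()`, `recall_metrics()`),
knowledge-source ablation (`source_ablation()`), a seeded synthetic-KB
generator with planted ground-truth chains (`generate_kb()`) and an
independent exhaustive oracle (`oracle_infer()`).  A command-line
front end lives at `inst/scripts/drugmoa`
(`infer`, `validate`, `ablate`, `evaluate`, `synth`, `export-asp`).

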