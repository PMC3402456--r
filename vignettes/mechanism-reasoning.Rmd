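---
title: "Mechanism-of-action reasoning: model, policies, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanism-of-action reasoning: model, policies, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drugmoa)
```

## The reasoning model

`drugmoa` infers new indications for existing drugs by chaining the
molecular consequences of drug–target binding through a signed,
directed interaction network until a disease-level conclusion is
reached.  The knowledge base holds five kinds of facts, each carried
by a typed tibble inside a `moa_kb` object:

* drug–target interactions with a pharmacological sign
  (`interaction(dipyridamole, inhibits, ada)` — antagonists inhibit,
  agonists induce);
* directed protein–protein interactions with the same two-valued sign;
* gene–disease associations qualified by an expression state
  (`relation(overexpressed(ada), associated_with, cancer)`);
* gene–bioprocess memberships
  (`relation(pnp, is_associated, pos_reg_cell_proliferation)`);
* class assertions: oncogenes, tumor suppressors, cancer-promoting and
  cancer-resisting bioprocesses.

For cancer KBs built from curated inputs,
`cancer_bioprocess_classes()` supplies the standard six Gene Ontology
instances: positive regulation of cell proliferation, negative
regulation of apoptosis and positive regulation of angiogenesis
promote cancer; their opposites resist it.

An inference is a chain of triggers `trigger(Dr, Action, Prot, Step)`
with consecutive steps.  Step 1 always comes from a drug–target edge
(rules R1a/R1b).  Steps 2..k propagate the perturbation along
protein–protein edges (R2a–R2d, see below).  The final step applies a
terminal rule (R3–R7: expression–disease association, oncogene,
suppressor, promoting/resisting bioprocess) and concludes
`treats(<class>)`.  The mirrored rules C1–C5 conclude
`promotes(<class>)` and feed contradiction handling.  A chain with
exactly two triggers is *direct*; longer chains are *indirect* —
classification is purely a function of chain length.

### Chain semantics

A solver over the same rules would assign one global step ordering per
model; this package instead enumerates **all minimal causal paths**
explicitly, one chain per path, deduplicated on the full trigger
sequence (including rule ids and supporting facts) and sorted by
(length, trigger sequence).  This reproduces the canonical step
sequences of the worked examples while making every chain
individually auditable: `validate_chains()` re-derives each step by
direct fact lookup, independent of the engine's traversal.  The same
conclusion reached through different supporting facts is reported as
distinct chains, because the support is the scientific content of the
hypothesis.

### Cycles and depth

Real interaction networks contain cycles; a chain therefore never
revisits a protein, and propagation stops at `max_depth` molecular
steps (default 5, so a chain has at most 6 triggers).  The default is
deliberately generous relative to the worked examples (2–3
triggers): signal-transduction arguments beyond a handful of hops are
rarely credible, but the bound is a policy knob, not a constant.

## Tunable policies

`engine_policy()` collects the knobs that genuinely change the
semantics:

* `max_depth` (integer ≥ 2, default 5) — molecular steps before the
  terminal rule.
* `contradiction_mode` (`"block"` default, `"flag"`, `"ignore"`) —
  what to do when the anti-mechanism rules also fire for a drug.
  `block` reproduces the phenomenon that known cancer drugs can be
  *missed* because of contradictory interactions: cladribine is
  an agonist of PNP, PNP sits in positive regulation of cell
  proliferation, so activating it argues *for* proliferation and the
  drug reports no treats chains.  `flag` returns both sides for human
  triage; `ignore` skips C-rules entirely.
* `inactivation_propagation` (default `TRUE`) — rule R2c: a protein
  that has been inactivated no longer induces its downstream partner,
  leaving the partner inactivated.  This loss-of-activator reading is
  the biologically standard one and is required for chains like
  "inhibit A, A normally induces oncogene B, so B is down".
* `double_negation_rule` (default `FALSE`) — rule R2d: inhibiting an
  inhibitor activates the downstream protein.  This presumes the
  downstream protein has basal activity being held down, which is not
  generally warranted; it is off unless the user opts in.

The defaults make propagation asymmetric in sign.  One observable
consequence: the exact mirror symmetry between treats machinery and
promotes machinery under inversion of the drug edge's sign holds at
every depth only under the fully symmetric policy (both flags on); at
depth 2 it holds under any policy.  The test suite checks both forms.

### Contradiction verdicts

The report verdict is `contradictory` only when a drug has *both*
treats and promotes chains; a drug with promotes chains alone (the
two-fact cladribine scenario) is `promoting_only`.  Blocking applies
to the contradictory case — with no treats chains there is nothing to
block — so both verdicts yield zero treats chains for such drugs.

## Disease-class mapping

Facts name specific diseases; the inference goal is a class.
`disease_class_map()` folds diseases into the class by explicit
membership or by case-insensitive substring patterns; the default
lexicon (`cancer`, `carcinoma`, `leukemia`, `lymphoma`, `tumor`,
`tumour`, `melanoma`, `sarcoma`, `glioma`) covers common oncology
nomenclature, is user-overridable via YAML/JSON config, and explicit
members take precedence over patterns.  A transparent lexicon was
chosen over any attempt at ontology alignment: the mapping is part of
the experiment and must be inspectable.

## Provenance and ablation

Every fact carries one of five source tags (`drugbank`,
`cancer_genes`, `go`, `text_mining`, `other`).  The fact dialect
cannot express tags, so parsed files get kind-based defaults matching
where each fact kind canonically originates (drug–target edges from
DrugBank, PPIs and disease relations from text mining, gene classes
from curated cancer-gene lists, bioprocess facts from GO); tabular
loaders can override per row.

`source_ablation()` re-runs the screen keeping drug–target facts
always (no initial trigger, no inference — a column without them could
infer nothing) and gating all other knowledge by tag.  Note an
implication of this design: an indirect chain that needs a text-mined
PPI *and* a curated terminal fact survives no singleton source subset,
so the union of singleton-subset screens equals the full screen only
when all chains are direct.  The suite asserts the union identity on
direct-only KBs and the (always true) subset-monotonicity property on
general KBs.

`recall_metrics()` reports recall against an original-indication label
set and a clinical-trial label set, plus the confirmed fraction of
inferences, each to one decimal; an empty label set yields `NA`, never
a silent zero.

## The synthetic generator and the oracle

`generate_kb()` draws seeded random KBs and plants ground-truth
chains whose support facts are inserted explicitly.  The default
`synth_params()` mimic the shape of a DrugBank-plus-text-mining KB at
roughly 1/50 scale: 19 drugs with ~1.8 drug–target edges each
(matching 1704 interactions over 943 drugs), 80 proteins with PPI
out-degree ~4 (matching ~17k PPIs over a few thousand proteins), ~4%
oncogene and suppressor fractions, and 15%/20% of proteins carrying
disease/bioprocess relations.  Planted paths use distinct drugs and
pairwise-distinct proteins; after an inactivating step only `induces`
edges are drawn so the chain stays derivable under the default
propagation flags.

What the generator does *not* emulate: text-mining noise (wrong
interactors, negation errors), gene-name ambiguity, hub-dominated
degree distributions, or correlated annotations.  Green property
tests therefore certify the *inference machinery*, not performance on
real extractions.

`oracle_infer()` is the correctness reference: it enumerates all
simple directed paths from the drug (naive recursive search over the
fact tables) and replays the rule definitions along each path with
straight-line code that shares no traversal logic with the engine —
only the final chain canonicalization is shared, so that chain sets
compare exactly.  It refuses KBs above 50 proteins.  The suite checks
engine/oracle equality of treats chains, promotes chains and verdicts
over 1000+ seeded KBs crossed with all 12 policy combinations
(3 contradiction modes × 2 propagation flags × 2 double-negation
flags), with KB sizes of 10–13 proteins and depths 2–5 — sized so the
exhaustive oracle stays exact and the whole sweep runs in minutes on
one core.

## Numerical and degenerate-input choices

* Atoms are normalized lowercase (`[a-z][a-z0-9_]*`); uppercase in a
  fact file is a syntax error (in the source dialect capitalised
  symbols are variables, which have no place in ground facts).
* Serialization orders facts by byte order of the rendered lines
  (radix sort, locale-independent), making output byte-stable and
  `parse ∘ serialize` the identity; evidence strings are not
  representable in the dialect and are excluded from fact identity.
* Empty inputs are legal everywhere: an empty file parses to an empty
  KB, an empty KB serializes to empty text, screens over zero drugs
  return empty tibbles.
* Duplicate facts collapse under set semantics (first evidence string
  wins); gene–disease rows without an expression-state qualifier are
  rejected rather than guessed, because the terminal rules are defined
  only for over-/under-expression.
* JSON output is deterministically ordered (drugs lexicographic,
  chains by canonical signature), so identical invocations are
  byte-identical.

## ASP export

`export_asp()` splices the serialized facts into a packaged static
rule file written in solver syntax, yielding a self-contained program
whose derived `trigger/4` atoms can be compared with the native engine
drug-by-drug (presence or absence of a treats conclusion — not
per chain, since a solver assigns one global step ordering while this
engine enumerates paths).  The export path is a cross-check facility;
the native engine is the implementation of record.

## Known limitations

* One disease class per run; no multi-disease goals and no ranking —
  the inference is Boolean by design.
* No gene-name normalization or alias resolution; identifiers are
  taken as given (one canonical symbol per gene).
* The headline numbers of a full-scale screen (hundreds of inferred
  drugs, recall against curated labels) depend on large external
  knowledge sources that are not bundled; the evaluation module
  computes the same metrics on any supplied KB and labels, and the
  acceptance script reproduces the desk-scale worked examples exactly.
* Drug–target facts without an agonist/antagonist annotation have no
  initial rule and are rejected by the loader rather than defaulted.
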