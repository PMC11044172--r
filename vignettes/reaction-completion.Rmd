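---
title: "Completing reaction records: heuristic balancing plus masked-language-model infilling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Completing reaction records: heuristic balancing plus masked-language-model infilling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Reaction databases curate what chemists report, and chemists rarely report
everything: byproducts (water from an esterification, HCl from a
substitution), co-reactants hidden in a "reagents" attribute, and counter-ions
are routinely missing from reaction records. A record such as

```
Nc1ccc(O)cc1.CC(=O)OC(C)=O>>CC(=O)Nc1ccc(O)cc1
```

(the acetylation of 4-aminophenol to paracetamol) is imbalanced: two carbons
and two oxygens present on the left never appear on the right, because the
acetic acid byproduct was not recorded. Downstream machine-learning models
trained on such records inherit the imbalance.

`rxncomplete` implements a two-stage completion workflow. A deterministic
heuristic balancer restores records that can be completed from a small library
of common side products or from the reagents and solvents already attached to
the record. Records the balancer cannot complete are handed to a masked
language model (MLM) over reaction SMILES, which proposes candidate missing
molecules; every proposal is re-verified by the balancer, so nothing enters
the output that does not conserve mass and charge exactly.

## Stage one: the heuristic balancer

### Element vectors and the hydrogen convention

A molecule is reduced to its heavy-atom counts plus net formal charge. Hydrogen
is deliberately ignored: in a reaction whose heavy atoms and charges balance,
hydrogen has no remaining degree of freedom (it is fixed by the molecular
formulas), so tracking it adds bookkeeping without information. The imbalance
of a record is the element-wise difference RHS − LHS, with charge carried as a
pseudo-element so a single code path covers atoms and electrons. Agents and
solvents never enter the sums until the balancer explicitly promotes one.

### Integer stoichiometry under a cap

When both sides carry the same element set, balancing reduces to finding a
positive integer null vector of the conservation matrix. The solver runs
Gauss-Jordan elimination and enumerates the free-variable grid, keeping the
solution with the smallest coefficient sum (ties: lexicographic order).
Coefficients are capped at 6: plausible small-molecule reactions do not need
large coefficients, and allowing them mostly manufactures false balances
(polymerizations, which do need them, are out of scope). The cap also keeps
the search trivially small.

### Help species and candidates

* **LHS surplus only** (a product is missing): help species from an ordered
  32-entry library — water through chlorobenzene, the most frequent side
  products of organic synthesis — are added to the RHS. Every single species
  (then, failing that, every pair; at most two per side) is solved, and the
  addition with the smallest total coefficient sum wins, with library order
  breaking ties. The minimal-sum rule matters: a deficit of C₂O₂ can be
  patched by 2 × CO as well as by one acetic acid, and the parsimonious,
  chemically sensible completion is the single molecule at coefficient 1.
* **RHS surplus only** (a reactant is missing): the recorded reagents and
  solvents are the candidates. Each is promoted to the reactants in turn,
  ranked by a confidence scorer, and the updated reaction re-enters the loop
  as a new record. When no candidates remain the record is classified
  `LHS_INSUFFICIENT`. Help species are *not* licensed here: inventing
  reactants produces false positives much more readily than reading them off
  the record.
* **Surplus on both sides**: candidates first (the LHS has priority), then
  help species are allowed on the LHS too — one at a time, each update
  re-entering the loop, where the remaining LHS surplus is typically resolved
  by an RHS help species. This ordering is what resolves the
  nitrile + methanol pattern (the Pinner mechanism): promote methanol, add
  water on the left, ammonia on the right, all coefficients 1. A flat search
  that tried single RHS help species first would instead balance the same
  record with ammonia alone at methanol coefficient 4 — materially valid,
  chemically wrong.

The loop is capped (default 3 re-entries) to guarantee termination; per-side
help additions are capped at 2. Every `COMPLETE_*` outcome carries its
completed record and passes an exact integer conservation check — there is no
tolerance anywhere in the balancer.

### The scorer contract

Candidate ranking is a pluggable `function(record) -> confidence in [0, 1]`.
The shipped default, `fallback_score()`, is an element-coverage heuristic:
the fraction of product heavy atoms whose element is available from the
reactants. An external learned atom mapper can be plugged in through the same
contract; the package does not depend on one, and all tests run with the
deterministic default.

## Stage two: the masked language model

### Tokenization

Reaction SMILES are tokenized with byte-pair encoding learned from the
training corpus: starting from single characters, the most frequent adjacent
pair is merged repeatedly (frequency ties broken lexicographically) until the
vocabulary budget is reached. Merges are free to span the `'.'` separator, so
tokens like `.O` or `)O.` arise; this is a feature, not an accident — the
model sees a reaction as one string and learns cross-molecule context. Four
special tokens (`<bos>`, `<eos>`, `<mask>`, `<pad>`) hold reserved ids. The
toy default budget is 256 tokens; a production vocabulary is a configuration
value, not a constant.

### Architecture and training

The model is a bidirectional transformer encoder implemented in this package
in plain R: token and position embeddings with layer norm, post-norm encoder
blocks (multi-head self-attention, GELU feed-forward), and a tied output head
projecting back onto the token embedding. Two presets ship: `"desk"`
(hidden 64, 2 layers, 4 heads, max length 128) and `"production"` (hidden 768,
6 layers, 12 heads, max length 512). The parameter count is a pure function
of the configuration and is reported at build time.

Training uses dynamic masking — a fresh random 15% of usable tokens per
epoch, specials never masked, the count rounded per sequence — and minimizes
the KL divergence between the one-hot truth and the predicted distribution at
masked positions only (unmasked positions contribute exactly zero gradient;
the test suite asserts this). Masking uses pure `<mask>` substitution with no
80/10/10 corruption split. The optimizer is Adam with global gradient-norm
clipping at 1; the loss is averaged (not summed) over masked positions so its
scale is batch-size invariant. The desk-scale default learning rate is 3e-3,
chosen for reliable convergence of the small preset on template corpora
(1e-3 converges too but needs several times more epochs). The corpus is
split 9 : 0.5 : 0.5 into train/validation/test; everything is seeded, and the
same seed reproduces the loss curve bitwise.

### Whole-molecule inference

The balancer names the deficient side; a single `@@@` placeholder is appended
to it (one missing molecule per record, by assumption — predicting several
explodes the search space; decodes that themselves contain `'.'` are still
accepted as multi-molecule proposals). Because the true token length of a
missing molecule is unknown, all lengths 1..N are enumerated: the placeholder
becomes L mask tokens, the model fills all of them in one greedy pass, and
the decoded string is kept if it parses as SMILES, deduplicated toward the
smallest L. Every surviving candidate is inserted into the record and handed
back to the balancer: candidates whose updated reaction is complete as-is
outrank candidates needing further balancer additions (fewer invented species
is the safer completion); within a tier the scorer decides, then smaller
token length, then lexicographic SMILES.

One tokenization subtlety is handled deliberately. Byte-pair merges cross
molecule boundaries, so in the full-string encoding a byproduct often lives
in a separator-inclusive token such as `.O`. The evaluation protocol
therefore masks the *token span covering the hidden molecule in the
full-string tokenization* (hidden-molecule testing), and the enumeration
protocol drops the separator adjoining the placeholder so the masked span
covers it; decoded spans are normalized by stripping leading/trailing syntax
characters before validity testing. Without this alignment a model that has
perfectly learned the masked-token task still fails whole-molecule recovery,
because the standalone-encoded context around the mask never occurs in
training.

### Hidden-molecule evaluation

On held-out complete reactions, each molecule of the evaluated side is hidden
once in turn (`A.B.C>>D.E` yields three LHS items and two RHS items), the
true token count is given to the model, and the prediction must match the
ground-truth SMILES exactly — a single wrong token makes a molecule
chemically different, so there is no partial credit. Rates are stratified by
token length: short (= 1), middle (2–10), long (> 10). Short molecules are
the operationally important stratum: real missing participants are mostly
small side species.

## The synthetic-reaction generator

No public reaction corpus ships with the package; the generator emulates one.
Five classic transformations — Fischer esterification, amide coupling,
anhydride acylation (amine or alcohol nucleophile), SN2 amination and
Williamson ether synthesis — are instantiated from pools of 10 alkyl and 6
aryl substituents (plus 4-aminophenol, so the anhydride template can emit the
paracetamol synthesis exactly), with Cl/Br/I variation where a halide is
involved. Every instantiation is verified exactly balanced at generation
time; generation aborts on any template error. Corruption deletes one known
participant (`drop_byproduct` on the RHS, `drop_reactant` on the LHS) and
records the truth, mirroring the hidden-molecule protocol.

What the generator does *not* emulate: condition metadata, yields,
stereochemistry, polymers, multi-step entries, and the long-tail diversity of
real patent data. Template byproducts intentionally overlap the default help
library so balancer-versus-model comparisons are meaningful. Passing tests on
this corpus demonstrate that the machinery is correct and that the model
learns template chemistry; they do not certify recovery rates on real
database records.

## Numerical and design choices

* Conservation checks are exact integer comparisons; the only tolerances in
  the package are the rational-arithmetic guard in the solver (1e-6 on
  integrality after elimination) and 1e-6 on softmax normalization in tests.
* Argmax ties in decoding resolve to the lowest token id; merge-frequency
  ties in BPE training resolve lexicographically; equal-confidence
  completions resolve to the smaller token length, then lexicographic
  SMILES. All tie-breaks are deterministic on purpose.
* Degenerate inputs: records must have non-empty reactants and products;
  `[H+]` (no heavy atoms) is a legal molecule whose element vector is pure
  charge; an all-zero conservation matrix (hydrogen-only chemistry) balances
  trivially at coefficients 1.
* The desk problem sizes used throughout the tests and the acceptance script
  — 5,000 generated reactions, vocabulary 256, 30 epochs, 120-record
  evaluation slices, 500-corruption recovery runs — are the package's chosen
  study conditions for a single-CPU workflow.
* Reactions whose molecules fail sanitization are tagged unusable and
  reported separately rather than aborting a batch run; duplicate reactions
  (canonical fragment multisets per field) are removed before statistics.

## Known limitations

* The balancer optimizes material balance, not mechanism: it will happily
  complete `CC(=O)O>>CCOC(C)=O.O` as a self-esterification at coefficient 2,
  and a both-side surplus can be patched by chemically meaningless help
  pairs. The same applies to the model stage: a syntactically valid but
  chemically wrong proposal survives whenever stoichiometric coefficients
  happen to balance it. These false positives are inherent to the approach;
  the structured per-record decision trail exists precisely so they can be
  audited.
* The MLM proposes molecules it has seen the shape of; long molecules
  (> 10 tokens) are effectively out of reach of masked infilling, which is
  acceptable because real missing participants are mostly small.
* OpenBabel's SMILES canonicalization differs cosmetically from other
  toolkits'; all comparisons inside the package are made in its own canonical
  forms, so cross-toolkit string equality should not be assumed.
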