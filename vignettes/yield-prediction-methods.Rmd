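---
title: "Graph-based yield prediction for HTE reaction tables: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-based yield prediction for HTE reaction tables: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hteyield)
```

## The problem

High-throughput experimentation (HTE) screens run one reaction class — for
example a Pd-catalyzed C–N or C–C cross-coupling — over the full cross of
small compound vocabularies (aryl halides × additives × ligands × bases),
holding temperature, time and stoichiometry fixed. The result is a dense
table of a few thousand reactions with percent yields. `hteyield` models
the map from the *molecular graphs of the reaction components* to the
yield, and provides the split constructions needed to ask the question that
actually matters for prospective use: does the model extrapolate to
compounds it has never seen?

## The model

Each component SMILES is parsed into a heavy-atom graph. Every atom receives
a tuple of circular-substructure identifiers at radii 0–3 (the
extended-connectivity construction: the radius-0 identifier hashes element,
formal charge, aromaticity, degree and hydrogen count; radius *r+1* hashes
the radius-*r* identifier together with the sorted (bond type, neighbor
identifier) pairs; an environment that stops growing keeps its identifier).
These identifiers are the keys of a trainable embedding table — the atom
input vector is the *sum* of its four radius embeddings, following the
convention of summed substructure vectors. An optional frozen table can be
loaded instead; identifiers unseen at training time map to a dedicated UNK
row, which extrapolation splits make unavoidable.

The network is a sequential combination of a message-passing neural
network (MPNN) and a transformer encoder:

1. **Shared MPNN.** All components of a reaction pass through one MPNN.
   For `L` rounds, each atom aggregates (by sum) messages
   `W_msg h_j + E_bond(type)` from its bonded neighbors and updates its
   state with a gated recurrent (GRU-style) update whose weights are
   shared across rounds. A `linear` update (`h W_self + message`) is
   available for closed-form testing. `L = 0` leaves the input projection
   untouched.
2. **Role embeddings and encoder.** The per-component atom matrices are
   concatenated row-wise and each row receives the additive embedding of
   its *reaction role* (aryl halide, additive, ligand, base, ...). No
   positional encoding is added, so the representation is invariant to
   component order and atom order by construction. `N` encoder blocks of
   multihead self-attention followed by a residual connection and layer
   normalization let atoms of different components interact. Attention is
   masked to rows of the same reaction, which is how variable numbers of
   components (and whole batches) are handled in one matrix: masked rows
   provably do not affect other reactions, and the package tests this by
   comparing batched against per-reaction forward passes.
3. **Readout.** The encoder output is summed over all rows (a
   permutation-invariant readout) and a small MLP maps the vector to one
   scalar. Training minimizes mean-squared error on yield/100 with Adam,
   early-stopping on a seeded 10 % validation fraction; predictions are
   reported ×100 on the percent scale.

A component recorded as `"none"` (a ligand-free well, say) is represented
as a single all-zero pseudo-atom, so shapes stay valid and the component
contributes nothing before the role embedding is added.

Roles are embedded once, before the first encoder block; the encoder
follows the reading of the architecture diagram in which attention + layer
normalization is the repeated unit, so no feed-forward sublayer is
inserted. The readout sums globally over all rows rather than
per-component; both choices were genuinely open and are recorded here as
this package's interpretation.

## Contrastive pretraining

The MPNN (and only the MPNN — the encoder and head always start fresh) can
be pretrained on an unlabeled corpus by molecular contrastive learning: two
independent augmentations of one molecule form a positive pair, all other
molecules in the batch are negatives, and the NT-Xent loss over cosine
similarities (temperature 0.1, two-layer projection head discarded
afterwards) pulls positives together. The corpus filter keeps molecules
with 10–30 heavy atoms inclusive, dropping and counting everything else.

Four augmentations are implemented, all at ratio 0.25 by default with
counts rounded up (`ceiling(ratio * n)`): atom masking (features replaced
by a MASK embedding; topology untouched), bond deletion, removal of one
connected subgraph, and **mini-subgraph removal**: repeatedly pick a random
surviving atom and delete it together with its surviving radius-1
neighbors, stopping at the first repetition that reaches or exceeds the
target. Because radius-3 identifiers of the surviving atoms still encode
the removed fragments, small local deletions degrade the view less than
one large hole — that is the point of the mini variant. Deleted atoms are
removed outright (the remnant may be disconnected, which is kept), at
least one atom always survives, and identifiers are recomputed on the
augmented graph. Centers are drawn uniformly from surviving atoms. Whether
the 0.25 ratio also applies to the three comparison augmentations was not
fixed externally; it is simply each method's default here and is
configurable per method.

## Splits

* `random_split()` — seeded uniform splits at percentage ratios
  (70:30 … 1:99). The fractional train count is rounded half-up by
  default; published per-ratio training sizes are not mutually consistent
  under any single rounding rule, so the rule is configurable and the
  realized sizes land in the manifest. For 1:99 a coverage flag
  rejection-samples (budget 1000 draws) until every training-compound
  structure also occurs in the test partition, keeping the tiny-train task
  an interpolation task; rejection sampling is this package's mechanism
  choice, since only the restriction itself was specified.
* `component_out_split()` — hold out all reactions containing given
  structures under one role (additive-out, reactant-out, ligand-out).
  Two-ligands-out or organoboron-out families are expressed through this
  one function with seeded random selections; no special-case code.
* `stest_splits()` — the rigorous family: halides partitioned into
  same-scaffold chloro/bromo/iodo triads (user-supplied, since the
  grouping rule is chemical, not inferable), a fixed five-additive test
  set, one split per (ligand, triad). Each test set is the full
  1 × 3 × 5 × 3 cross (45 reactions on a full table); each training set
  excludes every reaction containing the held-out ligand, any triad
  halide, or any test additive. On a 15 × 22 × 4 × 3 table this gives 20
  splits with 1836 training reactions each.

Leakage is enforced structurally and re-checked by registry scans in the
tests.

## Baselines and descriptors

* **Collision-free per-role ECFP6**: per role, every observed radius-≤3
  hash gets its own bit, positions ordered by decreasing hash value, so
  the hash→position map is a bijection and vector lengths differ across
  roles. The space is built on training data only and frozen (a joint
  train+test mode exists for exact-reproduction attempts); test-time
  hashes unseen at build time are dropped and counted. Bits are presence
  bits, not counts.
* **One-hot / random codebooks**: structure-free controls; a bit (or a
  seeded random vector) per compound, concatenated per role.
* **Regressors**: `randomForest` (500 trees) and `xgboost` with a small
  documented grid (`eta` ∈ {0.1, 0.3}, `max_depth` ∈ {4, 6}) chosen by
  seeded 3-fold cross-validation with early stopping. The boosting grid is
  a repository default, not an externally fixed value.

## Ensembles and evaluation

`run_evaluation()` trains a pool of models per split that differ only in
seed (the seed list is shared across methods), draws member subsets
without replacement to form ensembles, averages member predictions, and
reports the coefficient of determination `R² = 1 − SSres/SStot` per
ensemble with mean and SD across ensembles. `R²` here is the regression
coefficient of determination — not a squared correlation — and can be
negative. The full-scale protocol is a pool of 50, 10 members, 5 ensembles
(one ensemble for random-split families); the package defaults are a
desk-scale 6/3/2 and the full values are plain arguments.

Two outlier-analysis helpers operate on observed yields directly:
`component_swap_correlation()` pairs reactions identical in everything but
one role's compound and reports the Pearson correlation (both *r* and *r²*
are emitted, since both conventions circulate), and
`groupwise_yield_summary()` contrasts five-number yield summaries inside
each group with and without a marker component set — the pattern used to
show that a specific halide-triad × additive combination, absent from
training data, is unpredictable for any structure-based model.

## The synthetic fixture generator

`generate_fixture()` enumerates the full cross of per-role vocabularies of
real small molecules (halopyridines, isoxazole-type additives, phosphines,
amine bases, organoboron compounds including a potassium trifluoroborate
salt pair — so charges, aromatic systems and multi-fragment SMILES are all
exercised) and assigns
`yield = clip(base + Σ effects + Σ interactions + noise, 0, 100)`.
Per-compound effects default to N(0, 10) around a base of 50, noise SD
defaults to 5 yield points, and the realized law is returned so recovery
tests can assert against truth. Planted pairwise interactions reproduce
the outlier pattern above. What the generator deliberately does *not*
emulate: mechanistic chemistry, heteroscedastic assay noise, the long-born
zero-yield spike of real screens, or correlations between role effects.
Passing recovery tests therefore demonstrates that the machinery learns
recoverable component-driven signal — not that it reaches any particular
accuracy on real HTE data.

## Numerical choices and problem sizes

The neural stack runs on a small reverse-mode autodiff engine written for
this package (dense matrices, sparse aggregation operators); gradients are
verified against central finite differences to 1e-6 in the tests.
Attention masking uses additive −1e30 logits; softmax and log-sum-exp are
max-shifted; layer normalization uses ε = 1e-5; Adam uses the standard
(0.9, 0.999, 1e-8). Early stopping monitors validation MSE with patience
10 and restores the best parameters. All randomness flows through seeds:
the same seed reproduces initialization, batching, augmentation and hence
the whole parameter trajectory.

Canonical identity of structures (registry keys, split hold-outs) uses the
package's own canonical ranking: iterative neighborhood refinement seeded
from the radius-3 identifiers, with individualization of tied classes.
Atoms still tied after refinement are treated as topologically equivalent;
this is exact for the molecule classes that occur in reaction tables,
though highly regular graphs could in principle defeat it. Stereochemistry
and isotopes are parsed but ignored throughout — component identity in HTE
tables is constitutional.

Worked examples, tests and the acceptance script use deliberately small
problem sizes chosen as desk-scale defaults: a 10 × 10 × 4 zero-noise
fixture (400 reactions) with a 32-unit, L = 2, N = 1 model and a pool of
2 for signal recovery; a 200-molecule corpus and 5 epochs for contrastive
pretraining; the full 3960-reaction BHC-shaped table for split
construction. The full-scale hyper-parameters (128 units, L = 3, N = 2,
pool 50) are exposed in `model_config()` and `ensemble_spec()`; they are
this package's implementation choices, since the original architecture's
exact tuning tables are not published in text form.

## Known limitations

* The SMILES dialect covers the organic subset, bracket atoms with charge
  and explicit hydrogens, aromatic lowercase notation, rings (including
  `%nn`), branches and multi-fragment dots; stereo bonds are accepted and
  ignored, as are isotopes. Exotic valence states outside the default
  tables get hydrogen count 0 rather than an error.
* A trainable embedding table stands in for pretrained substructure
  vectors by default; loading a frozen table changes the UNK convention
  to a zero vector.
* The autodiff engine is single-threaded and tuned for the problem sizes
  above, not for full-scale screens; per-epoch cost grows quadratically
  with rows per batch, so small batches are the fast regime.
* Identifier hashes are 32-bit; collisions are astronomically unlikely at
  fixture scale and are checked (not assumed) for descriptor spaces.
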