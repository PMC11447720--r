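# hteyield

Yield prediction for high-throughput experimentation (HTE) reaction tables
from the molecular graphs of the reaction components.

HTE screens — Buchwald–Hartwig or Suzuki–Miyaura couplings run over the
full cross of aryl halides × additives × ligands × bases under fixed
conditions — produce dense tables of a few thousand reactions with percent
yields. The useful question for such models is not interpolation but
extrapolation: can the yield of a reaction containing a *new* compound be
predicted? `hteyield` implements, in pure R:

* **MPNN-Transformer yield model** — every component graph is processed by
  one shared message-passing neural network over per-atom
  circular-substructure identifiers (radii 0–3); the per-component atom
  matrices are concatenated, each row receives an additive *reaction-role*
  embedding, `N` transformer-encoder blocks (multihead self-attention +
  layer normalization, no positional encoding) let components interact,
  and a summation readout feeds an MLP head:
  `ŷ = MLP( Σ_rows Encoder( [MPNN(g₁); …; MPNN(g_k)] + E_role ) )`.
  The prediction is invariant to component order, atom order and batch
  composition by construction.
* **Contrastive pretraining** of the MPNN (NT-Xent over cosine
  similarities; two augmented views of one molecule are the positive
  pair), with four graph augmentations including **mini-subgraph
  removal**: repeatedly delete a random atom and its radius-1 neighbors
  until ⌈0.25·n⌉ atoms are gone — keeping deletions local so surviving
  radius-3 identifiers still encode the removed parts. A 10–30 heavy-atom
  corpus filter is included.
* **Split constructions** for rigorous evaluation: seeded random ratio
  splits (70:30 … 1:99, with a compound-coverage restriction for 1:99),
  component-out splits, and the ligand × halide-triad × additive family
  (20 splits of 45 test reactions on a full 15 × 22 × 4 × 3 table, with
  every held-out component excluded from training).
* **Baselines**: collision-free per-role ECFP6 reaction descriptors (one
  bit per observed hash, bijective by construction), one-hot and random
  compound codebooks, behind `randomForest` (500 trees) and `xgboost`
  (seeded CV over a small grid with early stopping).
* **Evaluation**: `R² = 1 − SSres/SStot`, a seed-pool ensemble protocol
  (pool → random member subsets → averaged predictions, mean ± SD across
  ensembles), component-swap yield correlations and group-wise outlier
  summaries.
* **Synthetic fixture generator**: full-combinatorial reaction tables over
  embedded vocabularies of real small molecules with a known yield law
  (`clip(base + Σ effects + interactions + noise, 0, 100)`), so the whole
  pipeline is testable offline with recoverable ground truth.

Everything tabular goes in and out as tibbles; fitted objects have
`tidy()`/`glance()` methods and results have `autoplot()`.

## Worked example

```r
library(hteyield)

voc <- fixture_vocabularies()
fx <- generate_fixture(fixture_spec(
  list(aryl_halide = voc$aryl_halide[1:10],
       additive    = voc$additive[1:10],
       ligand      = voc$ligand),
  noise_sd = 0, seed = 21))
ds <- fx$dataset
ds
#> <reaction_dataset> 400 reactions, roles: aryl_halide, additive, ligand
#>   registry sizes: aryl_halide=10, additive=10, ligand=4

sp <- random_split(ds, c(70, 30), seed = 2)
sp
#> <split_result:random_ratio> train 280 / test 120

cfg <- model_config(d_embed = 32, d_hidden = 32, L = 2, N = 1, n_heads = 2,
                    d_mlp = 32, dropout = 0, lr = 3e-3, batch_size = 8,
                    max_epochs = 60, patience = 15, seed = 7)
m <- train_yield_model(subset_dataset(ds, sp$train_idx), cfg)
m
#> <yield_model> d_embed=32 d_hidden=32 L=2 N=1 heads=2 | vocab 263 ids | roles: aryl_halide, additive, ligand
#>   best epoch: 36

preds <- predict_yields(m, ds, sp$test_idx)
head(preds, 3)
#> # A tibble: 3 × 2
#>   reaction_id predicted_yield
#>   <chr>                 <dbl>
#> 1 rxn0005                53.3
#> 2 rxn0010                31.2
#> 3 rxn0015                84.2

r_squared(ds$table$yield[sp$test_idx], preds$predicted_yield)
#> [1] 0.9979842
```

The fixture's yields are an additive function of the components (base 50,
per-compound effects, no noise), so a model that reads the component
structures should approach R² = 1 on a random split — and does. The
rigorous hold-out family on a full BHC-shaped table:

```r
bhc <- generate_fixture(fixture_spec(
  voc[c("aryl_halide", "additive", "ligand", "base")], seed = 11))$dataset
stest <- stest_splits(bhc,
                      triads = split(voc$aryl_halide, rep(1:5, each = 3)),
                      test_additives = voc$additive[c(1, 3, 5, 7, 11)])
head(split_summary(stest), 3)
#> # A tibble: 3 × 4
#>   split  kind  n_train n_test
#>   <chr>  <chr>   <int>  <int>
#> 1 sTest1 stest    1836     45
#> 2 sTest2 stest    1836     45
#> 3 sTest3 stest    1836     45
```

Each of the 20 test sets is one ligand × one chloro/bromo/iodo halide
triad × five fixed additives × all bases; the 1836 training reactions
contain none of the held-out components, so accuracy here measures
extrapolation to unseen reagents.

A command-line interface wrapping the same functions is installed at
`inst/cli/hteyield` (subcommands `fixture`, `split`, `pretrain`, `train`,
`predict`, `baseline`, `evaluate`; see `hteyield --help`).

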