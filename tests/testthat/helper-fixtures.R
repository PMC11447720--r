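# Shared fixtures, built once per test run (everything is generated in
# code; no data files).

voc_all <- fixture_vocabularies()

# Small combinatorial dataset with a known additive law (10 x 10 x 4 = 400
# reactions, no noise) used by model/baseline recovery tests.
small_fixture <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      spec <- fixture_spec(
        list(aryl_halide = voc_all$aryl_halide[1:10],
             additive = voc_all$additive[1:10],
             ligand = voc_all$ligand),
        noise_sd = 0, seed = 21
      )
      memo <<- generate_fixture(spec)
    }
    memo
  }
})

# Full BHC-shaped combinatorial table (15 x 22 x 4 x 3 = 3960).
bhc_fixture <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      spec <- fixture_spec(
        voc_all[c("aryl_halide", "additive", "ligand", "base")],
        seed = 11
      )
      memo <<- generate_fixture(spec)
    }
    memo
  }
})

bhc_triads <- function() split(voc_all$aryl_halide, rep(1:5, each = 3))
bhc_test_additives <- function() voc_all$additive[c(1, 3, 5, 7, 11)]

# Tiny model configuration for fast training in tests.
tiny_config <- function(...) {
  defaults <- list(d_embed = 16L, d_hidden = 16L, L = 2L, N = 1L,
                   n_heads = 2L, d_mlp = 16L, dropout = 0, lr = 5e-3,
                   batch_size = 8L, max_epochs = 10L, patience = 10L,
                   seed = 3L)
  do.call(model_config, utils::modifyList(defaults, list(...)))
}

# A barely-initialized model (1 epoch on a handful of reactions): the
# architecture invariances hold for any parameter values.
init_model <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      ds <- small_fixture()$dataset
      memo <<- train_yield_model(
        hteyield:::subset_dataset(ds, 1:12),
        tiny_config(max_epochs = 1L, val_fraction = 0)
      )
    }
    memo
  }
})

expect_no_leakage <- function(ds, split) {
  testthat::expect_length(hteyield:::scan_leakage(ds, split), 0)
}
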