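# The R^2 metric, ensemble protocol, evaluation workflow and the
# outlier/correlation analyses.

test_that("r_squared matches its definition and the worked example", {
  expect_equal(r_squared(c(0, 50, 100), c(10, 50, 90)), 0.96)
  obs <- c(3, 7, 2, 9)
  expect_equal(r_squared(obs, obs), 1)
  expect_equal(r_squared(obs, rep(mean(obs), 4)), 0)
  # can be negative for a bad model
  expect_lt(r_squared(obs, rev(obs) * 3), 0)
  expect_error(r_squared(c(1, 1), c(1, 2)), class = "hteyield_metric_error")
  expect_error(r_squared(1, 1), class = "hteyield_metric_error")
})

test_that("r_squared agrees with a brute-force two-pass computation", {
  set.seed(12)
  for (k in 1:20) {
    n <- sample(5:200, 1)
    obs <- rnorm(n, 50, 20); pred <- obs + rnorm(n, 0, 10)
    ss_res <- 0; ss_tot <- 0; m <- sum(obs) / n
    for (i in seq_len(n)) {
      ss_res <- ss_res + (obs[i] - pred[i])^2
      ss_tot <- ss_tot + (obs[i] - m)^2
    }
    expect_equal(r_squared(obs, pred), 1 - ss_res / ss_tot,
                 tolerance = 1e-12)
  }
})

test_that("ensemble prediction is the member mean and stays in the envelope", {
  expect_equal(ensemble_predict(cbind(c(40, 10))), c(40, 10))  # identity
  expect_equal(ensemble_predict(list(c(40, 0), c(60, 10))), c(50, 5))
  expect_error(ensemble_predict(list()), class = "hteyield_metric_error")
  set.seed(3)
  for (k in 1:20) {
    m <- matrix(runif(8 * 5, 0, 100), 8, 5)
    e <- ensemble_predict(m)
    expect_true(all(e >= apply(m, 1, min) - 1e-12 &
                      e <= apply(m, 1, max) + 1e-12))
  }
})

test_that("the evaluation workflow reports per-ensemble accuracy deterministically", {
  fx <- small_fixture()
  ds <- fx$dataset
  sp <- random_split(ds, c(70, 30), seed = 2)
  factory <- function(train_ds, seed) {
    cb <- build_codebook(train_ds, "one_hot", seed = seed)
    f <- fit_baseline(codebook_descriptors(train_ds, cb),
                      train_ds$table$yield, "forest", ntree = 100, seed = seed)
    function(dsx, idx) predict(f, codebook_descriptors(dsx, cb, idx))
  }
  ens <- ensemble_spec(pool_size = 2, members_per_ensemble = 2,
                       n_ensembles = 1)
  rep1 <- run_evaluation(ds, list(rand = sp), factory, ens)
  expect_equal(nrow(rep1$results), 1)   # degenerate spec: one R^2
  expect_equal(rep1$summary$sd_r2, 0)
  rep2 <- run_evaluation(ds, list(rand = sp), factory, ens)
  expect_identical(rep1$results$r2, rep2$results$r2)
  expect_gt(rep1$summary$mean_r2, 0.5)
  # tidy/glance surfaces
  expect_equal(nrow(tidy(rep1)), 1)
  expect_equal(glance(rep1)$n_splits, 1)
})

test_that("structure-free descriptors on structure-only signal score near zero", {
  # yields depend only on the aryl halide; a codebook seeing only the
  # ligand column carries no signal at all
  voc <- fixture_vocabularies()
  eff <- dplyr::bind_rows(
    tibble::tibble(role = "aryl_halide", structure = voc$aryl_halide[1:6],
                   effect = seq(-25, 25, length.out = 6)),
    tibble::tibble(role = "ligand", structure = voc$ligand,
                   effect = rep(0, 4))
  )
  fx <- generate_fixture(fixture_spec(
    list(aryl_halide = voc$aryl_halide[1:6], ligand = voc$ligand),
    effects = eff, noise_sd = 2, seed = 8))
  ds <- fx$dataset
  sp <- random_split(ds, c(50, 50), seed = 1)
  factory <- function(train_ds, seed) {
    lig_only <- train_ds
    lig_only$roles <- "ligand"
    cb <- build_codebook(lig_only, "one_hot", seed = seed)
    f <- fit_baseline(codebook_descriptors(train_ds, cb),
                      train_ds$table$yield, "forest", ntree = 100, seed = seed)
    function(dsx, idx) predict(f, codebook_descriptors(dsx, cb, idx))
  }
  rep <- run_evaluation(ds, list(s = sp), factory,
                        ensemble_spec(pool_size = 2, members_per_ensemble = 2,
                                      n_ensembles = 1))
  expect_lt(abs(rep$summary$mean_r2), 0.15)
})

test_that("evaluation reports serialize and restore", {
  fx <- small_fixture()
  ds <- fx$dataset
  sp <- random_split(ds, c(70, 30), seed = 9)
  factory <- function(train_ds, seed) {
    m <- mean(train_ds$table$yield)
    function(dsx, idx) rep(m + seed, length(idx))
  }
  rep <- run_evaluation(ds, list(a = sp), factory,
                        ensemble_spec(pool_size = 3, members_per_ensemble = 2,
                                      n_ensembles = 2))
  path <- withr::local_tempfile(fileext = ".json")
  write_eval_report(rep, path)
  rep2 <- read_eval_report(path)
  expect_equal(rep2$results$r2, rep$results$r2)
  expect_equal(rep2$summary$mean_r2, rep$summary$mean_r2)
})

test_that("swap correlation recovers constructed component relationships", {
  voc <- fixture_vocabularies()
  base_effects <- function(b1, b2, b3) dplyr::bind_rows(
    tibble::tibble(role = "aryl_halide", structure = voc$aryl_halide[1:8],
                   effect = stats::rnorm(8, 0, 15)),
    tibble::tibble(role = "additive", structure = voc$additive[1:8],
                   effect = stats::rnorm(8, 0, 15)),
    tibble::tibble(role = "organoboron", structure = voc$organoboron[1:3],
                   effect = c(b1, b2, b3))
  )
  set.seed(42)
  # identical effects, no noise: swapping the organoboron changes nothing
  fx <- generate_fixture(fixture_spec(
    list(aryl_halide = voc$aryl_halide[1:8], additive = voc$additive[1:8],
         organoboron = voc$organoboron[1:3]),
    effects = base_effects(4, 4, 4), noise_sd = 0, seed = 13))
  sw <- component_swap_correlation(fx$dataset, "organoboron",
                                   voc$organoboron[1], voc$organoboron[2])
  expect_equal(sw$n_pairs, 64)
  expect_gt(sw$pearson_r, 0.999)

  # self-swap on a deduplicated table: identical pairs, r = 1
  sw_self <- component_swap_correlation(fx$dataset, "organoboron",
                                        voc$organoboron[1], voc$organoboron[1])
  expect_equal(sw_self$pearson_r, 1)

  expect_error(component_swap_correlation(fx$dataset, "organoboron",
                                          voc$organoboron[1], "CCCC"),
               class = "hteyield_data_error")
})

test_that("independent equal-variance noise halves the swap correlation", {
  # yields for the two swapped compounds share a common component-driven
  # signal of variance s^2 and carry independent noise of variance s^2
  # each: analytic correlation = s^2 / (s^2 + s^2) = 0.5
  set.seed(7)
  n_ctx <- 200
  signal <- stats::rnorm(n_ctx, 50, 10)
  noise_a <- stats::rnorm(n_ctx, 0, 10)
  noise_b <- stats::rnorm(n_ctx, 0, 10)
  # 200 structurally distinct context molecules: secondary amines
  # C_a-N-C_b with unique unordered chain-length pairs {a, b}
  contexts <- vapply(seq_len(n_ctx), function(k) {
    a <- (k - 1) %/% 10 + 1
    b <- a + (k - 1) %% 10 + 1
    paste0(strrep("C", a), "N", strrep("C", b))
  }, character(1))
  tab <- tibble::tibble(
    context = rep(contexts, 2),
    swap = rep(c("Cc1ccccc1", "CCc1ccccc1"), each = n_ctx),
    yield = pmin(100, pmax(0, c(signal + noise_a, signal + noise_b)))
  )
  ds <- reaction_dataset(tab, c("context", "swap"))
  sw <- component_swap_correlation(ds, "swap", "Cc1ccccc1", "CCc1ccccc1")
  expect_equal(sw$n_pairs, n_ctx)
  expect_lt(abs(sw$pearson_r - 0.5), 0.1)
})

test_that("group-wise summaries recover a planted marker offset", {
  voc <- fixture_vocabularies()
  outlier_add <- voc$additive[3]
  marker_halides <- voc$aryl_halide[1:3]
  ia <- tidyr::expand_grid(
    role_a = "aryl_halide", structure_a = marker_halides,
    role_b = "additive", structure_b = outlier_add, delta = 35
  )
  fx <- generate_fixture(fixture_spec(
    list(aryl_halide = voc$aryl_halide[1:6], additive = voc$additive[1:5],
         base = voc$base),
    interactions = ia, noise_sd = 1, seed = 6))
  gs <- groupwise_yield_summary(fx$dataset, "additive", "aryl_halide",
                                marker_halides)
  canon_out <- hteyield:::canonicalize_structures(outlier_add)
  med <- function(grp, wm) gs$median[gs$group == grp & gs$with_marker == wm]
  gap_outlier <- med(canon_out, TRUE) - med(canon_out, FALSE)
  expect_gt(gap_outlier, 25)
  other <- setdiff(unique(gs$group), canon_out)
  gaps_other <- vapply(other, function(g) abs(med(g, TRUE) - med(g, FALSE)),
                       numeric(1))
  expect_lt(max(gaps_other), 15)

  # marker covering every reaction: non-marker side flagged empty
  gs_all <- groupwise_yield_summary(fx$dataset, "additive", "aryl_halide",
                                    voc$aryl_halide[1:6])
  expect_true(all(gs_all$n[!gs_all$with_marker] == 0))

  # invariance to row order
  ds_shuf <- fx$dataset
  set.seed(1)
  perm <- sample(n_reactions(ds_shuf))
  ds_shuf$table <- ds_shuf$table[perm, ]
  gs_shuf <- groupwise_yield_summary(ds_shuf, "additive", "aryl_halide",
                                     marker_halides)
  expect_equal(dplyr::arrange(gs_shuf, group, with_marker),
               dplyr::arrange(gs, group, with_marker))
})
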