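# Collision-free ECFP6 descriptor spaces, compound codebooks, and the
# forest/boosting adapters.

test_that("the per-role hash-to-position map is a bijection", {
  ds <- small_fixture()$dataset
  space <- build_ecfp6_space(ds)
  for (role in space$roles) {
    pos <- space$positions[[role]]
    # brute-force scan: positions dense 1..len, each hash distinct
    expect_equal(sort(unname(pos)), seq_along(pos))
    expect_false(anyDuplicated(names(pos)) > 0)
    # ordering is by decreasing hash value
    expect_true(all(diff(as.numeric(names(pos))) < 0))
  }
  # lengths differ across roles (different chemistries)
  expect_gt(length(unique(space$lengths)), 1)
})

test_that("single-compound and disjoint-chemistry spaces behave", {
  ds1 <- reaction_dataset(
    tibble::tibble(solvent = c("C", "C"), yield = c(1, 2)), "solvent")
  sp1 <- build_ecfp6_space(ds1)
  # methane: one atom, identical environment at every radius => 1 hash
  expect_equal(unname(sp1$lengths), 1L)

  ds2 <- reaction_dataset(
    tibble::tibble(a = c("CCCC", "CCC"), b = c("c1ccncc1", "c1ccccc1"),
                   yield = c(1, 2)), c("a", "b"))
  sp2 <- build_ecfp6_space(ds2)
  expect_length(intersect(names(sp2$positions$a), names(sp2$positions$b)), 0)
})

test_that("reaction descriptors concatenate per-role blocks", {
  ds <- small_fixture()$dataset
  space <- build_ecfp6_space(ds)
  X <- reaction_descriptors(ds, space, 1:10)
  expect_equal(ncol(X), sum(space$lengths))
  expect_true(all(X %in% c(0, 1)))
  expect_equal(attr(X, "dropped_hashes"), 0)

  # absent component => all-zero block for that role
  tab <- ds$table[1:2, ]
  tab$ligand[1] <- NA
  ds2 <- ds; ds2$table <- tab
  X2 <- reaction_descriptors(ds2, space, 1:2)
  off <- cumsum(space$lengths)
  lig_cols <- (off[["additive"]] + 1):off[["ligand"]]
  expect_true(all(X2[1, lig_cols] == 0))
  expect_gt(sum(X2[2, lig_cols]), 0)
})

test_that("novel test-time environments are dropped and counted", {
  ds <- small_fixture()$dataset
  space <- build_ecfp6_space(ds)
  # a bromo-thiophene halide never seen when the space was built
  novel <- tibble::tibble(
    aryl_halide = "Brc1cccs1",
    additive = voc_all$additive[1], ligand = voc_all$ligand[1],
    yield = 50
  )
  ds_novel <- reaction_dataset(novel, ds$roles)
  Xn <- reaction_descriptors(ds_novel, space)
  expect_gt(attr(Xn, "dropped_hashes"), 0)
  expect_equal(ncol(Xn), sum(space$lengths))
})

test_that("one-hot and random codebooks have the stated structure", {
  ds <- small_fixture()$dataset
  cb <- build_codebook(ds, "one_hot")
  for (role in cb$roles) {
    bk <- cb$books[[role]]
    expect_true(all(rowSums(bk) == 1))
    expect_true(all(colSums(bk) <= 1))
    expect_equal(nrow(unique(bk)), nrow(bk))
  }
  expect_error(build_codebook(ds, "one_hot", dim = 2),
               class = "hteyield_data_error")

  r1 <- build_codebook(ds, "random", dim = 100, seed = 7)
  r2 <- build_codebook(ds, "random", dim = 100, seed = 7)
  expect_identical(r1$books, r2$books)
  bk <- r1$books$aryl_halide
  expect_equal(ncol(bk), 100)
  expect_false(any(duplicated(bk)))

  X <- codebook_descriptors(ds, r1, 1:4)
  expect_equal(ncol(X), sum(vapply(r1$books, ncol, integer(1))))
})

test_that("forest recovers a purely additive yield law", {
  fx <- small_fixture()
  ds <- fx$dataset
  sp <- random_split(ds, c(70, 30), seed = 2)
  cb <- build_codebook(ds, "one_hot")
  Xtr <- codebook_descriptors(ds, cb, sp$train_idx)
  Xte <- codebook_descriptors(ds, cb, sp$test_idx)
  fit <- fit_baseline(Xtr, ds$table$yield[sp$train_idx], "forest",
                      ntree = 300, seed = 4)
  r2 <- r_squared(ds$table$yield[sp$test_idx], predict(fit, Xte))
  expect_gt(r2, 0.7)
})

test_that("codebooks carry no structural information (assignment symmetry)", {
  fx <- small_fixture()
  ds <- fx$dataset
  sp <- random_split(ds, c(70, 30), seed = 5)
  y_tr <- ds$table$yield[sp$train_idx]
  y_te <- ds$table$yield[sp$test_idx]
  r2s <- numeric(2)
  for (k in 1:2) {
    cb <- build_codebook(ds, "one_hot")
    if (k == 2) {
      # permute which unit vector belongs to which compound
      set.seed(11)
      for (role in cb$roles) {
        bk <- cb$books[[role]]
        cb$books[[role]] <- bk[sample(nrow(bk)), , drop = FALSE]
        rownames(cb$books[[role]]) <- rownames(bk)
      }
    }
    fit <- fit_baseline(codebook_descriptors(ds, cb, sp$train_idx), y_tr,
                        "forest", ntree = 200, seed = 4)
    r2s[k] <- r_squared(y_te, predict(fit, codebook_descriptors(ds, cb, sp$test_idx)))
  }
  expect_lt(abs(r2s[1] - r2s[2]), 0.05)
})

test_that("degenerate targets and boosting early stopping behave", {
  X <- matrix(rnorm(200), 20, 10)
  expect_error(fit_baseline(X, rep(50, 20), "forest"),
               class = "hteyield_data_error")
  set.seed(2)
  y <- rnorm(20)  # pure noise: early stopping should fire quickly
  fit <- fit_baseline(X, y, "boosting", nrounds = 200, seed = 3)
  expect_lte(fit$meta$best_iter, 200)
  expect_true(is.finite(predict(fit, X)[1]))
})
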