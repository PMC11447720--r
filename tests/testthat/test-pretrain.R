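# Corpus filtering, the four graph augmentations, the contrastive loss,
# and the pretraining loop.

test_that("the corpus filter keeps 10-30 heavy atoms inclusive", {
  mols <- c(
    paste(rep("C", 9), collapse = ""),    # 9 heavy atoms: dropped
    paste(rep("C", 10), collapse = ""),   # boundary: kept
    paste(rep("C", 30), collapse = ""),   # boundary: kept
    paste(rep("C", 31), collapse = ""),   # dropped
    "not_a_smiles(",                      # unparsable: dropped, counted
    "c1ccc2ccccc2c1CC"                    # 12: kept
  )
  kept <- filter_corpus(mols)
  expect_equal(as.character(kept), mols[c(2, 3, 6)])
  expect_equal(unname(attr(kept, "dropped")["parse"]), 1)
  expect_equal(unname(attr(kept, "dropped")["size"]), 2)
})

test_that("mini-subgraph removal deletes local regions up to the ceiling target", {
  corpus <- fixture_corpus(60, seed = 31)
  for (k in seq_along(corpus)) {
    g <- graph_from_smiles(corpus[k])
    n <- nrow(g$atoms)
    a <- augment(g, augmentation_config("mini_subgraph_removal", 0.25,
                                        seed = 100 + k))
    target <- ceiling(0.25 * n)
    expect_gte(length(a$deleted), target)
    expect_equal(nrow(a$atoms), n - length(a$deleted))
    # locality: every deleted atom within distance 1 of a chosen center
    D <- hteyield:::graph_distances(g)
    expect_true(all(vapply(a$deleted, function(d) {
      min(D[d, a$centers]) <= 1
    }, logical(1))))
    # stop-at-crossing: dropping the last center's neighborhood would
    # leave the count below target
    last_center <- a$centers[length(a$centers)]
    before_last <- length(a$deleted) -
      sum(a$deleted %in% c(last_center,
                           which(D[last_center, ] == 1)))
    expect_lt(before_last, target)
  }
})

test_that("all augmentations are seed-deterministic", {
  g <- graph_from_smiles("Cc1ccc2c(cnn2C2CCCCO2)c1B(O)O")
  for (m in c("atom_masking", "bond_deletion", "subgraph_removal",
              "mini_subgraph_removal")) {
    cfg <- augmentation_config(m, 0.25, seed = 17)
    a1 <- augment(g, cfg); a2 <- augment(g, cfg)
    expect_identical(a1$atoms, a2$atoms, label = m)
    expect_identical(a1$bonds, a2$bonds, label = m)
  }
})

test_that("augmentation counts follow the ceiling rule", {
  g12 <- graph_from_smiles("c1ccc2ccccc2c1CC")  # 12 atoms
  am <- augment(g12, augmentation_config("atom_masking", 0.25, seed = 2))
  expect_equal(sum(am$atoms$masked), 3)
  expect_equal(nrow(am$atoms), 12)  # masking does not delete
  sg <- augment(g12, augmentation_config("subgraph_removal", 0.25, seed = 2))
  expect_equal(length(sg$deleted), 3)
  # single-bond graph at ratio 0.25: ceiling(0.25 * 1) = 1 bond removed
  g2 <- graph_from_smiles("CC")
  bd <- augment(g2, augmentation_config("bond_deletion", 0.25, seed = 1))
  expect_equal(nrow(bd$bonds), 0)
  # deleting the whole graph is refused
  g1 <- graph_from_smiles("CC")
  expect_error(augment(g1, augmentation_config("subgraph_removal", 0.99,
                                               seed = 1)),
               class = "hteyield_augment_error")
})

test_that("surviving atoms keep deterministic identifiers after augmentation", {
  g <- graph_from_smiles("COc1ccc(-c2cnoc2)cc1")
  cfg <- augmentation_config("mini_subgraph_removal", 0.25, seed = 5)
  a <- augment(g, cfg)
  rebuilt <- graph_from_smiles(a$canonical_smiles)
  expect_identical(
    sort(apply(a$env_ids, 1, paste, collapse = ",")),
    sort(apply(rebuilt$env_ids, 1, paste, collapse = ","))
  )
})

test_that("NT-Xent matches hand-evaluated cases", {
  # B = 2, orthogonal unit pairs (u,u), (v,v), tau = 1: each anchor sees
  # its positive at similarity 1 and two negatives at 0
  u <- c(1, 0); v <- c(0, 1)
  z <- rbind(u, v, u, v)
  expect_equal(contrastive_loss(z, 1), -log(exp(1) / (exp(1) + 2)),
               tolerance = 1e-12)
  # all embeddings identical: softmax is uniform over 2B - 1 candidates
  zi <- matrix(1, 6, 3)
  expect_equal(contrastive_loss(zi, 0.5), log(5), tolerance = 1e-12)
  # temperature sharpening: separated pairs, loss non-increasing in 1/tau
  set.seed(4)
  za <- rbind(diag(4), diag(4) + matrix(rnorm(16, 0, 0.01), 4))
  taus <- c(1, 0.5, 0.2, 0.1)
  losses <- vapply(taus, function(t) contrastive_loss(za, t), numeric(1))
  expect_true(all(diff(losses) <= 1e-8))
  expect_error(contrastive_loss(matrix(1, 2, 3)),
               class = "hteyield_loss_error")
})

test_that("the loss is invariant to reordering pairs within the batch", {
  set.seed(9)
  B <- 5
  z <- matrix(rnorm(2 * B * 8), 2 * B, 8)
  l0 <- contrastive_loss(z, 0.3)
  perm <- sample(B)
  zp <- rbind(z[perm, , drop = FALSE], z[B + perm, , drop = FALSE])
  expect_equal(contrastive_loss(zp, 0.3), l0, tolerance = 1e-12)
})

test_that("short pretraining reduces the loss and separates positives", {
  corpus <- fixture_corpus(80, seed = 1)
  mcfg <- model_config(d_embed = 16L, d_hidden = 16L, L = 2L, N = 0L,
                       n_heads = 1L, dropout = 0, seed = 1L)
  ck <- pretrain_mpnn(corpus, augmentation_config("mini_subgraph_removal",
                                                  0.25, seed = 11),
                      mcfg, epochs = 4, batch_size = 16)
  expect_lt(ck$history$loss[nrow(ck$history)], ck$history$loss[1])

  # held-out molecules: positive-pair cosine similarity beats mean negative
  held <- fixture_corpus(20, seed = 99)
  graphs <- lapply(held, graph_from_smiles)
  set.seed(5)
  views <- c(lapply(graphs, function(g)
               hteyield:::augment_impl(g, "mini_subgraph_removal", 0.25)),
             lapply(graphs, function(g)
               hteyield:::augment_impl(g, "mini_subgraph_removal", 0.25)))
  emb <- embed_molecules(ck, views)
  emb <- emb / sqrt(rowSums(emb^2))
  sim <- emb %*% t(emb)
  B <- length(graphs)
  pos <- sim[cbind(seq_len(B), B + seq_len(B))]
  neg <- sim[upper.tri(sim)]
  neg <- neg[!neg %in% pos]
  expect_gt(mean(pos), mean(neg))

  # checkpoint round-trip: identical embeddings
  path <- withr::local_tempfile(fileext = ".rds")
  write_mpnn_checkpoint(ck, path)
  ck2 <- read_mpnn_checkpoint(path)
  expect_identical(embed_molecules(ck2, graphs[1:3]),
                   embed_molecules(ck, graphs[1:3]))
})

test_that("a pretrained checkpoint initializes a trainable yield model", {
  corpus <- fixture_corpus(40, seed = 3)
  mcfg <- tiny_config(N = 1L)
  ck <- pretrain_mpnn(corpus, augmentation_config(seed = 2), mcfg,
                      epochs = 1, batch_size = 16)
  ds <- hteyield:::subset_dataset(small_fixture()$dataset, 1:30)
  m <- train_yield_model(ds, tiny_config(N = 1L, max_epochs = 3L),
                         pretrained_mpnn = ck)
  expect_s3_class(m, "yield_model")
  expect_identical(m$vocab, ck$vocab)
  p <- predict_yields(m, ds, 1:5)
  expect_true(all(is.finite(p$predicted_yield)))
})
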