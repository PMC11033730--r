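small_cfg <- function(...) {
  model_config(hidden_dim = 16L, message_depth = 2L, epochs = 5L,
               learning_rate = 3e-3, batch_size = 32L, seed = 1L, ...)
}

test_that("analytic gradients match finite differences", {
  set.seed(3)
  mols <- molecule_table(c("a", "b", "c", "d"),
                         c("Cc1ccccc1O", "O=[N+]([O-])c1ccc(C)cc1",
                           "CCOC(=O)c1ccncc1", "CC(C)c1ccc2ccccc2c1"))
  graphs <- oncorepurpose:::.mol_graphs(mols$canonical_smiles)
  gb <- oncorepurpose:::.graph_batch(graphs)
  aux <- matrix(rnorm(4 * 3), 4, 3)
  y <- c(1, 0, 1, 0)
  w <- oncorepurpose:::.init_weights(oncorepurpose:::.N_ATOM_F,
                                     oncorepurpose:::.N_BOND_F, 8L, 3L, 2L)
  loss <- function(w) {
    p <- oncorepurpose:::.mpnn_forward(w, gb, aux, 2L, 2L)$p
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }
  fw <- oncorepurpose:::.mpnn_forward(w, gb, aux, 2L, 2L, keep = TRUE)
  gr <- oncorepurpose:::.mpnn_backward(w, gb, aux, y, fw, 2L, 2L)
  eps <- 1e-6
  for (nm in names(gr)) {
    for (k in sample(length(gr[[nm]]), min(5, length(gr[[nm]])))) {
      wp <- w; wp[[nm]][k] <- wp[[nm]][k] + eps
      wm <- w; wm[[nm]][k] <- wm[[nm]][k] - eps
      fd <- (loss(wp) - loss(wm)) / (2 * eps)
      expect_equal(gr[[nm]][k], fd, tolerance = 1e-4)
    }
  }
})

test_that("the network learns a planted substructure motif", {
  ds <- motif_dataset(n = 200, seed = 4)
  cfg <- model_config(hidden_dim = 64L, message_depth = 2L, epochs = 20L,
                      learning_rate = 3e-3, seed = 1L)
  m <- train_mpnn(ds, NULL, cfg)
  p <- predict(m, ds$molecules)
  expect_gte(compute_metrics(ds$labels, p)$auc, 0.95)
})

test_that("without aux blocks predictions ignore any supplied feature table", {
  ds <- motif_dataset(n = 60, n_templates = 10, seed = 6)
  m <- train_mpnn(ds, NULL, small_cfg())
  b <- make_benchmark(benchmark_config(n_drugs = 60, n_scaffold_templates = 10,
                                       seed = 6))
  pca <- fit_pca(b$dti, k = 8)
  amfp <- fit_amfp(b$ddi, d = 8, epochs = 5, seed = 1)
  ft <- suppressMessages(build_feature_table(b$catalogue, b$dti, b$ddi, pca, amfp))
  # same molecules either way; feature table keys by id
  p0 <- predict(m, ds$molecules)
  p1 <- predict(m, ds$molecules, features = ft)
  expect_identical(p0, p1)
})

test_that("random labels with random features stay near chance on held-out data", {
  aucs <- c()
  for (seed in 1:3) {
    mols <- generate_molecules(150, 30, seed = 100 + seed)
    set.seed(200 + seed)
    y <- stats::setNames(c(0L, 1L, sample(0:1, 148, replace = TRUE)), mols$id)
    ds <- structure(list(molecules = mols, labels = y,
                         provenance = stats::setNames(rep("x", 150), mols$id)),
                    class = "labeled_dataset")
    plan <- scaffold_split(ds, seed = seed)
    tr <- oncorepurpose:::.subset_dataset(ds, split_ids(plan, "train"))
    te <- split_ids(plan, "test")
    cfg <- small_cfg(); cfg$seed <- seed
    m <- train_mpnn(tr, NULL, cfg)
    p <- predict(m, ds$molecules[ds$molecules$id %in% te, ])
    aucs <- c(aucs, compute_metrics(y[te], p[te])$auc)
  }
  expect_gte(mean(aucs), 0.35)
  expect_lte(mean(aucs), 0.65)
})

test_that("ensemble scores are exactly the member mean and members differ", {
  ds <- motif_dataset(n = 100, n_templates = 15, seed = 8)
  ens <- train_ensemble(ds, NULL, small_cfg(), n_members = 2L)
  expect_identical(ens$member_seeds, c(1L, 2L))
  p_ens <- predict(ens, ds$molecules)
  p1 <- predict(ens$members[[1]], ds$molecules)
  p2 <- predict(ens$members[[2]], ds$molecules)
  expect_equal(p_ens, (p1 + p2) / 2, tolerance = 1e-8)
  expect_gt(max(abs(p1 - p2)), 0)
  # singleton ensembles reduce to the single model
  ens1 <- train_ensemble(ds, NULL, small_cfg(), n_members = 1L)
  expect_equal(predict(ens1, ds$molecules),
               predict(ens1$members[[1]], ds$molecules))
})

test_that("prediction is deterministic, bounded, and robust to bad SMILES", {
  ds <- motif_dataset(n = 60, n_templates = 10, seed = 9)
  m <- train_mpnn(ds, NULL, small_cfg())
  p <- predict(m, ds$molecules)
  expect_true(all(p >= 0 & p <= 1))
  dupl <- ds$molecules[c(1, 1, 2), ]
  dupl$id <- c("x1", "x2", "x3")
  pd <- predict(m, dupl)
  expect_equal(unname(pd[["x1"]]), unname(pd[["x2"]]))
  bad <- ds$molecules[1:2, ]
  bad$smiles[2] <- "not_a_smiles"
  bad$id <- c("ok", "bad")
  expect_warning(pb <- predict(m, bad), "parsed")
  expect_false(is.na(pb[["ok"]]))
  expect_true(is.na(pb[["bad"]]))
})

test_that("training on a single class is rejected", {
  ds <- motif_dataset(n = 40, n_templates = 8, seed = 10)
  ds$labels[] <- 1L
  expect_error(train_mpnn(ds, NULL, small_cfg()), "single class")
})

test_that("identical config and seed reproduce identical models", {
  ds <- motif_dataset(n = 50, n_templates = 10, seed = 11)
  m1 <- train_mpnn(ds, NULL, small_cfg())
  m2 <- train_mpnn(ds, NULL, small_cfg())
  expect_identical(m1$weights, m2$weights)
})
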