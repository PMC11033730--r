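rand_dti <- function(n, t, seed, density = 0.3) {
  set.seed(seed)
  hits <- which(matrix(runif(n * t) < density, n, t), arr.ind = TRUE)
  interaction_matrix(sprintf("d%03d", 1:n), sprintf("t%03d", 1:t),
                     cbind(sprintf("d%03d", hits[, 1]), sprintf("t%03d", hits[, 2])),
                     "DTI")
}

test_that("interaction matrices enforce their shape invariants", {
  expect_error(interaction_matrix(c("a", "b"), c("a", "b"),
                                  cbind("a", "a"), "DDI"), "diagonal")
  expect_error(interaction_matrix(c("a", "b"), c("x", "y"),
                                  cbind("a", "z"), "DTI"), "unknown id")
  ddi <- interaction_matrix(c("a", "b", "c"), c("a", "b", "c"),
                            cbind("a", "b"), "DDI")
  expect_true(Matrix::isSymmetric(ddi$mat))
})

test_that("interaction matrices round-trip through TSV triplets", {
  dti <- rand_dti(12, 6, seed = 1)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_interactions(dti, tmp)
  back <- read_interactions(tmp, paste0(tmp, ".rows"), paste0(tmp, ".cols"), "DTI")
  expect_equal(as.matrix(back$mat), as.matrix(dti$mat))
})

test_that("PCA explained variance matches an eigendecomposition oracle", {
  for (seed in 1:3) {
    dti <- rand_dti(50, 30, seed)
    pm <- fit_pca(dti, k = 10)
    ev <- eigen(cov(as.matrix(dti$mat)), symmetric = TRUE, only.values = TRUE)$values
    expect_equal(sum(pm$explained_variance_ratio), sum(ev[1:10]) / sum(ev),
                 tolerance = 1e-10)
    expect_equal(pm$explained_variance_ratio, ev[1:10] / sum(ev), tolerance = 1e-10)
  }
})

test_that("rank-1 data explains everything with one component; full rank sums to 1", {
  ids <- sprintf("d%02d", 1:8)
  # half the drugs hit the same 4 targets, the rest hit nothing: rank 1
  prs2 <- do.call(rbind, lapply(c(1, 3, 5, 7), function(i) cbind(ids[i], sprintf("t%02d", 1:4))))
  dti2 <- interaction_matrix(ids, sprintf("t%02d", 1:8), prs2, "DTI")
  pm2 <- fit_pca(dti2, k = 1)
  expect_equal(pm2$explained_variance_ratio[1], 1.0, tolerance = 1e-8)
  full <- fit_pca(rand_dti(20, 10, 5), k = 10)
  expect_equal(sum(full$explained_variance_ratio), 1.0, tolerance = 1e-8)
  expect_error(fit_pca(rand_dti(20, 10, 5), k = 11), "exceeds")
})

test_that("pca_project centers, matches a dense oracle, and reconstruction improves with k", {
  dti <- rand_dti(30, 15, seed = 7)
  pm <- fit_pca(dti, k = 15)
  expect_equal(pca_project(pm, pm$mean), rep(0, 15))
  X <- as.matrix(dti$mat)
  row <- X[4, ]
  oracle <- as.numeric((row - colMeans(X)) %*% pm$rotation)
  expect_equal(pca_project(pm, row), oracle, tolerance = 1e-10)
  errs <- vapply(c(2, 5, 10, 15), function(k) {
    pk <- fit_pca(dti, k = k)
    rec <- pk$mean + as.numeric(pk$rotation %*% pca_project(pk, row))
    sum((row - rec)^2)
  }, 0)
  expect_true(all(diff(errs) <= 1e-8))
})

test_that("AMFP with propagation disabled returns the raw factorization", {
  g <- planted_ddi(n = 60, seed = 2)
  m <- fit_amfp(g$ddi, d = 8, epochs = 10, propagation_weight = 0, seed = 3)
  expect_identical(m$embeddings, m$raw)
})

test_that("amfp_score is symmetric, bounded, and separates planted blocks", {
  g <- planted_ddi(n = 100, seed = 5)
  m <- fit_amfp(g$ddi, d = 8, epochs = 60, seed = 3)
  s_ab <- amfp_score(m, g$ids[1], g$ids[60])
  s_ba <- amfp_score(m, g$ids[60], g$ids[1])
  expect_equal(s_ab, s_ba)
  expect_true(s_ab > 0 && s_ab < 1)
  expect_error(amfp_score(m, g$ids[1], "nope"), "unknown")
  Z <- m$embeddings
  S <- Z %*% t(Z) + outer(unname(m$bias), unname(m$bias), "+") + m$global_bias
  same <- outer(g$comm, g$comm, "==")
  ut <- upper.tri(S)
  expect_gt(mean(plogis(S[same & ut])), mean(plogis(S[!same & ut])))
})

test_that("a single planted edge is reconstructed above the non-edge median", {
  ids <- sprintf("s%02d", 1:12)
  # one edge between two nodes; remaining nodes share a background clique
  prs <- rbind(cbind("s01", "s02"),
               t(combn(ids[5:12], 2)))
  ddi <- interaction_matrix(ids, ids, prs, "DDI")
  m <- fit_amfp(ddi, d = 4, epochs = 200, seed = 8)
  s12 <- amfp_score(m, "s01", "s02")
  nonedges <- t(combn(ids, 2))
  key <- paste(prs[, 1], prs[, 2])
  ne <- nonedges[!(paste(nonedges[, 1], nonedges[, 2]) %in% key), , drop = FALSE]
  ne_scores <- vapply(seq_len(nrow(ne)), function(r) amfp_score(m, ne[r, 1], ne[r, 2]), 0)
  expect_gt(s12, stats::median(ne_scores))
})

test_that("embedding cosine similarity is higher within planted communities", {
  aucs <- c()
  for (seed in 1:3) {
    g <- planted_ddi(n = 100, seed = seed)
    m <- fit_amfp(g$ddi, d = 8, epochs = 60, seed = seed)
    E <- m$embeddings / sqrt(rowSums(m$embeddings^2))
    C <- E %*% t(E)
    same <- outer(g$comm, g$comm, "==")
    ut <- upper.tri(C)
    aucs <- c(aucs, mean(C[same & ut]) - mean(C[!same & ut]))
  }
  expect_gt(mean(aucs), 0)
})

test_that("imputation copies identical neighbors verbatim and falls back to means", {
  lib <- molecule_table(c("a", "b", "c"),
                        c("Cc1ccccc1", "Oc1ccncc1", "CCCCCCCCCC"))
  store <- list(dti = matrix(1:6, 3, 2, dimnames = list(c("a", "b", "c"), NULL)),
                ddi = matrix(7:12, 3, 2, dimnames = list(c("a", "b", "c"), NULL)))
  dup <- molecule_table("q", "CC1=CC=CC=C1")      # identical to a
  im <- impute_features(dup[1, ], store, lib)
  expect_equal(im$dti_block, store$dti["a", ])
  expect_identical(im$dti_provenance$kind, "neighbor")
  expect_identical(im$dti_provenance$neighbor_id, "a")
  expect_equal(im$dti_provenance$similarity, 1.0)
  far <- molecule_table("z", "N")                  # nothing similar
  imf <- impute_features(far[1, ], store, lib)
  expect_identical(imf$dti_provenance$kind, "average")
  expect_equal(imf$dti_block, colMeans(store$dti))
  expect_equal(imf$ddi_block, colMeans(store$ddi))
  # average imputation stays within the stored per-coordinate bounds
  expect_true(all(imf$dti_block >= apply(store$dti, 2, min) &
                  imf$dti_block <= apply(store$dti, 2, max)))
})

test_that("blocks impute independently: direct DTI with neighbor DDI", {
  lib <- molecule_table(c("a", "b"), c("Cc1ccccc1", "CCO"))
  store <- list(dti = matrix(1:4, 2, 2, dimnames = list(c("a", "q"), NULL)),
                ddi = matrix(5:8, 2, 2, dimnames = list(c("a", "b"), NULL)))
  q <- molecule_table("q", "CC1=CC=CC=C1")
  im <- impute_features(q[1, ], store, rbind(lib, q))
  expect_identical(im$dti_provenance$kind, "direct")
  expect_identical(im$ddi_provenance$kind, "neighbor")
  expect_identical(im$ddi_provenance$neighbor_id, "a")
})

test_that("the feature table is complete, 320-dim, and masked ids drive provenance", {
  b <- make_benchmark(benchmark_config(n_drugs = 100, n_scaffold_templates = 15,
                                       seed = 17))
  pca <- fit_pca(b$dti, k = 64)
  amfp <- suppressWarnings(fit_amfp(b$ddi, d = 256, epochs = 20, seed = 2))
  ft <- suppressMessages(build_feature_table(b$catalogue, b$dti, b$ddi, pca, amfp))
  expect_equal(ncol(ft$features), 320)
  expect_equal(nrow(ft$features), 100)
  expect_false(anyNA(ft$features))
  expect_setequal(names(ft$dti_provenance)[ft$dti_provenance != "direct"],
                  b$ground_truth$masked_dti_ids)
  expect_setequal(names(ft$ddi_provenance)[ft$ddi_provenance != "direct"],
                  b$ground_truth$masked_ddi_ids)
})
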