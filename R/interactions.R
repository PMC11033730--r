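## Interaction feature compression: sparse DTI / DDI containers, PCA
## compression of the drug x target matrix, logistic adjacency
## factorization with neighbor propagation (AMFP) for the drug-drug
## graph, and similarity-based imputation for drugs missing from either
## matrix.

#' Sparse binary interaction matrix
#'
#' Wraps a sparse 0/1 matrix with id labels.  `kind = "DTI"` is a
#' rectangular drugs x targets matrix; `kind = "DDI"` is a square
#' symmetric drug adjacency with empty diagonal.
#'
#' @param row_ids,col_ids Identifier vectors fixing row/column order.
#' @param pairs Two-column matrix or data.frame of (row id, col id)
#'   interacting pairs.
#' @param kind `"DTI"` or `"DDI"`.
#' @return An `interaction_matrix` (list with `mat`, `kind`).
#' @export
interaction_matrix <- function(row_ids, col_ids, pairs, kind = c("DTI", "DDI")) {
  kind <- match.arg(kind)
  row_ids <- as.character(row_ids); col_ids <- as.character(col_ids)
  if (anyDuplicated(row_ids) || anyDuplicated(col_ids)) .stopf("duplicate ids in matrix axes")
  pairs <- as.matrix(pairs)
  i <- match(as.character(pairs[, 1]), row_ids)
  j <- match(as.character(pairs[, 2]), col_ids)
  if (anyNA(i) || anyNA(j)) .stopf("interaction pair references unknown id")
  if (kind == "DDI") {
    if (!identical(row_ids, col_ids)) .stopf("DDI matrix must have row_ids == col_ids")
    if (any(i == j)) .stopf("DDI diagonal must be empty")
    ii <- c(i, j); jj <- c(j, i)   # symmetrize
    i <- ii; j <- jj
  }
  keep <- !duplicated(cbind(i, j))
  mat <- Matrix::sparseMatrix(i = i[keep], j = j[keep], x = 1,
                              dims = c(length(row_ids), length(col_ids)),
                              dimnames = list(row_ids, col_ids))
  structure(list(mat = mat, kind = kind), class = "interaction_matrix")
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat(sprintf("%s interaction matrix: %d x %d, %d nonzeros\n", x$kind,
              nrow(x$mat), ncol(x$mat), length(x$mat@x)))
  invisible(x)
}

#' Read / write interaction matrices
#'
#' Supports MatrixMarket coordinate files (`.mtx`, with sidecar id lists)
#' and TSV triplets `row_id<TAB>col_id<TAB>1`.
#'
#' @param path Matrix file (`.mtx` or `.tsv`).
#' @param row_ids,col_ids Id vectors (or sidecar file paths, one id per
#'   line) fixing axis order; required for `.mtx`, optional for TSV.
#' @param kind `"DTI"` or `"DDI"`.
#' @export
read_interactions <- function(path, row_ids = NULL, col_ids = NULL, kind = c("DTI", "DDI")) {
  kind <- match.arg(kind)
  as_ids <- function(x) if (is.character(x) && length(x) == 1L && file.exists(x)) readLines(x) else x
  row_ids <- as_ids(row_ids); col_ids <- as_ids(col_ids)
  if (grepl("\\.mtx$", path)) {
    m <- as(Matrix::readMM(path), "CsparseMatrix")
    if (is.null(row_ids) || is.null(col_ids)) .stopf("mtx input needs row_ids and col_ids")
    idx <- Matrix::summary(m)
    pairs <- cbind(row_ids[idx$i], col_ids[idx$j])
  } else {
    tr <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    pairs <- cbind(as.character(tr[[1]]), as.character(tr[[2]]))
    if (is.null(row_ids)) row_ids <- sort(unique(pairs[, 1]))
    if (is.null(col_ids)) col_ids <- if (kind == "DDI") row_ids else sort(unique(pairs[, 2]))
  }
  if (kind == "DDI") {
    # triplets may list each undirected pair once; constructor symmetrizes
    pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  }
  interaction_matrix(row_ids, col_ids, pairs, kind)
}

#' @rdname read_interactions
#' @param im An `interaction_matrix`.
#' @export
write_interactions <- function(im, path) {
  idx <- Matrix::summary(im$mat)
  rid <- rownames(im$mat)[idx$i]; cid <- colnames(im$mat)[idx$j]
  if (im$kind == "DDI") {
    keep <- idx$i < idx$j
    rid <- rid[keep]; cid <- cid[keep]
  }
  ord <- order(rid, cid)
  writeLines(paste(rid[ord], cid[ord], "1", sep = "\t"), path)
  writeLines(rownames(im$mat), paste0(path, ".rows"))
  writeLines(colnames(im$mat), paste0(path, ".cols"))
  invisible(path)
}

# ---- PCA over the DTI matrix ------------------------------------------

#' Fit PCA on a drug x target interaction matrix
#'
#' Mean-centered (unscaled) principal component analysis of the binary
#' DTI matrix, keeping the top `k` axes as the dense drug representation.
#'
#' @param dti `interaction_matrix` of kind DTI.
#' @param k Number of components (default 64).
#' @return A `pca_model`: `mean` (per-target), `rotation`
#'   (targets x k, orthonormal columns), `explained_variance_ratio`.
#' @export
fit_pca <- function(dti, k = 64L) {
  stopifnot(inherits(dti, "interaction_matrix"))
  if (dti$kind != "DTI") .stopf("fit_pca expects a DTI matrix")
  X <- as.matrix(dti$mat)
  if (all(X == 0)) .stopf("degenerate input: all-zero DTI matrix")
  if (k > min(dim(X))) .stopf("k = %d exceeds min(dim) = %d", k, min(dim(X)))
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = k)
  totvar <- sum(apply(X, 2, var))
  structure(list(mean = pc$center,
                 rotation = pc$rotation[, seq_len(k), drop = FALSE],
                 explained_variance_ratio = pc$sdev[seq_len(k)]^2 / totvar,
                 k = as.integer(k)),
            class = "pca_model")
}

#' Project a drug's target-interaction row onto the PCA axes
#'
#' @param model A `pca_model`.
#' @param drug_row Binary vector over targets (or matrix, drugs in rows).
#' @return Numeric k-vector (or matrix).
#' @export
pca_project <- function(model, drug_row) {
  if (is.null(dim(drug_row))) {
    if (length(drug_row) != length(model$mean)) .stopf("row length mismatch")
    as.numeric((drug_row - model$mean) %*% model$rotation)
  } else {
    if (ncol(drug_row) != length(model$mean)) .stopf("row length mismatch")
    sweep(as.matrix(drug_row), 2, model$mean) %*% model$rotation
  }
}

# ---- AMFP: adjacency matrix factorization with propagation ------------

#' Embed a drug-drug interaction graph (AMFP)
#'
#' Logistic matrix factorization of the DDI adjacency: the probability of
#' an interaction between drugs i and j is
#' `sigmoid(u_i . u_j + b_i + b_j + c)`.  Embeddings, biases and the
#' global offset are fitted by Adam on observed pairs plus sampled
#' non-pairs (`negative_ratio` negatives per positive).  After
#' optimization each embedding is smoothed one step toward its neighbor
#' mean: `z_i = (1 - alpha) u_i + alpha mean_j(u_j)`; isolated drugs keep
#' `u_i`.
#'
#' @param ddi `interaction_matrix` of kind DDI.
#' @param d Embedding dimension (default 256).
#' @param epochs,learning_rate Adam schedule.
#' @param negative_ratio Sampled non-edges per observed edge.
#' @param propagation_weight Neighbor-mean weight `alpha` in `[0, 1]`.
#' @param seed RNG seed controlling init and negative sampling.
#' @return An `amfp_model` with `embeddings` (drugs x d, propagated),
#'   `raw` (pre-propagation), `bias`, `global_bias`, `trained_ids`.
#' @export
fit_amfp <- function(ddi, d = 256L, epochs = 100L, learning_rate = 0.05,
                     negative_ratio = 1, propagation_weight = 0.5, seed = 1L) {
  stopifnot(inherits(ddi, "interaction_matrix"))
  if (ddi$kind != "DDI") .stopf("fit_amfp expects a DDI matrix")
  A <- ddi$mat
  n <- nrow(A)
  ids <- rownames(A)
  idx <- Matrix::summary(A)
  pos <- cbind(idx$i[idx$i < idx$j], idx$j[idx$i < idx$j])
  if (!nrow(pos)) .stopf("degenerate input: empty DDI graph")
  if (d >= n) .warnf("embedding dimension %d >= %d drugs (over-parameterized)", d, n)
  set.seed(seed)
  U <- matrix(rnorm(n * d, sd = 0.1), n, d)
  b <- numeric(n)
  dens <- nrow(pos) / (n * (n - 1) / 2)
  cglob <- stats::qlogis(min(max(dens, 1e-6), 1 - 1e-6))
  edge_key <- pos[, 1] * n + pos[, 2]
  n_neg <- ceiling(nrow(pos) * negative_ratio)
  # Adam state
  mU <- vU <- matrix(0, n, d); mb <- vb <- numeric(n); mc <- vc <- 0
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (ep in seq_len(epochs)) {
    neg <- matrix(0, 0, 2)
    while (nrow(neg) < n_neg) {
      i <- sample.int(n, 2 * n_neg, replace = TRUE)
      j <- sample.int(n, 2 * n_neg, replace = TRUE)
      sw <- i > j; tmp <- i[sw]; i[sw] <- j[sw]; j[sw] <- tmp
      ok <- i < j & !((i * n + j) %in% edge_key)
      neg <- rbind(neg, cbind(i[ok], j[ok]))
    }
    neg <- neg[seq_len(n_neg), , drop = FALSE]
    pi_ <- c(pos[, 1], neg[, 1]); pj <- c(pos[, 2], neg[, 2])
    y <- c(rep(1, nrow(pos)), rep(0, n_neg))
    s <- rowSums(U[pi_, , drop = FALSE] * U[pj, , drop = FALSE]) + b[pi_] + b[pj] + cglob
    g <- (.sigmoid(s) - y) / length(y)
    gU <- rowsum(rbind(g * U[pj, , drop = FALSE], g * U[pi_, , drop = FALSE]),
                 group = c(pi_, pj), reorder = FALSE)
    grpU <- as.integer(rownames(gU))
    dU <- matrix(0, n, d); dU[grpU, ] <- as.matrix(gU)
    db <- numeric(n)
    tb <- rowsum(c(g, g), group = c(pi_, pj), reorder = FALSE)
    db[as.integer(rownames(tb))] <- tb
    dc <- sum(g)
    t <- ep
    adam <- function(m, v, gr) {
      m <- b1 * m + (1 - b1) * gr
      v <- b2 * v + (1 - b2) * gr^2
      list(m = m, v = v,
           step = learning_rate * (m / (1 - b1^t)) / (sqrt(v / (1 - b2^t)) + eps))
    }
    aU <- adam(mU, vU, dU); mU <- aU$m; vU <- aU$v; U <- U - aU$step
    ab <- adam(mb, vb, db); mb <- ab$m; vb <- ab$v; b <- b - ab$step
    ac <- adam(mc, vc, dc); mc <- ac$m; vc <- ac$v; cglob <- cglob - ac$step
  }
  degs <- Matrix::rowSums(A)
  Z <- U
  if (propagation_weight > 0) {
    nb_mean <- as.matrix(A %*% U) / pmax(degs, 1)
    has_nb <- degs > 0
    Z[has_nb, ] <- (1 - propagation_weight) * U[has_nb, , drop = FALSE] +
      propagation_weight * nb_mean[has_nb, , drop = FALSE]
  }
  rownames(Z) <- rownames(U) <- ids
  structure(list(embeddings = Z, raw = U, bias = stats::setNames(b, ids),
                 global_bias = cglob, propagation_weight = propagation_weight,
                 d = as.integer(d), trained_ids = ids, seed = as.integer(seed)),
            class = "amfp_model")
}

#' Reconstructed interaction probability between two embedded drugs
#'
#' @param model An `amfp_model`.
#' @param i,j Drug ids (order irrelevant).
#' @return Probability in `(0, 1)`.
#' @export
amfp_score <- function(model, i, j) {
  if (!(i %in% model$trained_ids) || !(j %in% model$trained_ids))
    .stopf("unknown drug id: %s", if (i %in% model$trained_ids) j else i)
  zi <- model$embeddings[i, ]; zj <- model$embeddings[j, ]
  .sigmoid(sum(zi * zj) + model$bias[[i]] + model$bias[[j]] + model$global_bias)
}

# ---- imputation and the feature table ---------------------------------

#' Impute auxiliary feature blocks for one drug
#'
#' Each block (DTI projection, DDI embedding) is handled independently:
#' present in the store -> direct; else copied from the chemically most
#' similar drug possessing that block when its Tanimoto similarity
#' reaches `threshold`; else the element-wise mean over all drugs
#' possessing the block.
#'
#' @param drug One-row molecule table for the drug to featurize.
#' @param store List with numeric matrices `dti` and `ddi` (rows named by
#'   drug id) of directly computed blocks.
#' @param library Molecule table covering the drugs in `store`.
#' @param threshold Similarity threshold (default 0.7).
#' @return List with `dti_block`, `ddi_block`, `dti_provenance`,
#'   `ddi_provenance` (each provenance a list with `kind` and, for
#'   neighbors, `neighbor_id` and `similarity`).
#' @export
impute_features <- function(drug, store, library, threshold = 0.7) {
  if (is.null(store$dti) || is.null(store$ddi) || !nrow(store$dti) || !nrow(store$ddi))
    .stopf("feature store must contain non-empty dti and ddi blocks")
  one <- function(block) {
    M <- store[[block]]
    if (drug$id %in% rownames(M))
      return(list(vec = M[drug$id, ], prov = list(kind = "direct")))
    lib <- library[library$id %in% rownames(M) & library$id != drug$id, , drop = FALSE]
    hit <- if (nrow(lib)) most_similar(drug, lib, threshold) else NULL
    if (!is.null(hit))
      return(list(vec = M[hit$neighbor_id, ],
                  prov = list(kind = "neighbor", neighbor_id = hit$neighbor_id,
                              similarity = hit$similarity)))
    list(vec = colMeans(M), prov = list(kind = "average"))
  }
  dti <- one("dti"); ddi <- one("ddi")
  list(dti_block = dti$vec, ddi_block = ddi$vec,
       dti_provenance = dti$prov, ddi_provenance = ddi$prov)
}

#' Build the auxiliary feature table for a set of drugs
#'
#' Combines the 64-dim PCA-DTI projection and the 256-dim AMFP-DDI
#' embedding per drug (default dimensions), imputing blocks for drugs
#' absent from either matrix.
#'
#' @param drugs Molecule table of drugs to featurize.
#' @param dti,ddi Interaction matrices.
#' @param pca Fitted `pca_model`.
#' @param amfp Fitted `amfp_model`.
#' @param threshold Imputation similarity threshold.
#' @return A `feature_table`: list with `features` (drugs x (k + d)
#'   matrix, columns `dti_*` then `ddi_*`), `dti_provenance`,
#'   `ddi_provenance` (character vectors: `"direct"`, `"neighbor"`,
#'   `"average"`), and `neighbor_detail`.
#' @export
build_feature_table <- function(drugs, dti, ddi, pca, amfp, threshold = 0.7) {
  proj <- pca_project(pca, dti$mat)
  rownames(proj) <- rownames(dti$mat)
  store <- list(dti = proj, ddi = amfp$embeddings)
  k <- ncol(proj); d <- ncol(amfp$embeddings)
  feats <- matrix(NA_real_, nrow(drugs), k + d,
                  dimnames = list(drugs$id, c(paste0("dti_", seq_len(k)),
                                              paste0("ddi_", seq_len(d)))))
  dp <- ddp <- character(nrow(drugs))
  detail <- list()
  # one fingerprint pass; imputation reuses it for every missing block
  fps <- morgan_fingerprint(drugs$canonical_smiles, ids = drugs$id)
  fill_block <- function(block, cols) {
    M <- store[[block]]
    prov <- rep("direct", nrow(drugs))
    have <- drugs$id %in% rownames(M)
    feats[have, cols] <<- M[drugs$id[have], , drop = FALSE]
    miss <- which(!have)
    if (!length(miss)) return(prov)
    donors <- drugs$id[have]
    sims <- .tanimoto_cross(fps[drugs$id[miss]], fps[donors])
    for (q in seq_along(miss)) {
      r <- miss[q]
      s <- sims[q, ]
      mx <- if (length(s)) max(s) else -Inf
      if (mx >= threshold) {
        nb <- sort(donors[s == mx])[1]
        feats[r, cols] <<- M[nb, ]
        prov[r] <- "neighbor"
        detail[[drugs$id[r]]][[block]] <<- list(kind = "neighbor", neighbor_id = nb,
                                                similarity = unname(mx))
      } else {
        feats[r, cols] <<- colMeans(M)
        prov[r] <- "average"
        detail[[drugs$id[r]]][[block]] <<- list(kind = "average")
      }
    }
    prov
  }
  dp <- fill_block("dti", seq_len(k))
  ddp <- fill_block("ddi", k + seq_len(d))
  message(sprintf("feature table: dti %s | ddi %s",
                  paste(names(table(dp)), table(dp), sep = "=", collapse = " "),
                  paste(names(table(ddp)), table(ddp), sep = "=", collapse = " ")))
  structure(list(features = feats,
                 dti_provenance = stats::setNames(dp, drugs$id),
                 ddi_provenance = stats::setNames(ddp, drugs$id),
                 neighbor_detail = detail,
                 k = k, d = d),
            class = "feature_table")
}

#' Write a feature table as TSV
#'
#' `id`, the numeric feature columns, then the two provenance columns.
#' @param ft A `feature_table`.
#' @param path TSV path.
#' @export
write_feature_table <- function(ft, path) {
  df <- data.frame(id = rownames(ft$features), ft$features,
                   dti_provenance = unname(ft$dti_provenance),
                   ddi_provenance = unname(ft$ddi_provenance),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
}
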