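## Fingerprint baselines (gradient boosting, SVM) and 2D physicochemical
## descriptors.

#' 2D physicochemical descriptors
#'
#' A fixed-length vector of cheap structure-derived descriptors per
#' molecule (molecular weight over heavy atoms, atom/bond/ring counts,
#' heteroatom counts, ring fraction, rotatable bonds, degree
#' statistics).  Raw values; classifiers z-score them on training data.
#'
#' @param mols Molecule table.
#' @return Numeric matrix, rows named by id.
#' @export
physchem_descriptors <- function(mols) {
  masses <- c(H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
              F = 18.998, Si = 28.085, P = 30.974, S = 32.06,
              Cl = 35.45, Br = 79.904, I = 126.904)
  graphs <- .mol_graphs(mols$canonical_smiles)
  out <- t(vapply(graphs, function(g) {
    m <- masses[g$elem]; m[is.na(m)] <- 12
    nb <- nrow(g$bonds)
    n_rot <- if (nb) sum(g$bonds[, 3] == 1 & !g$ring_bond &
                           g$degree[g$bonds[, 1]] > 1 & g$degree[g$bonds[, 2]] > 1) else 0
    c(mol_weight = sum(m),
      n_atoms = length(g$elem),
      n_bonds = nb,
      n_rings = nb - length(g$elem) + 1,       # cyclomatic number (connected)
      n_N = sum(g$elem == "N"),
      n_O = sum(g$elem == "O"),
      n_S = sum(g$elem == "S"),
      n_halogen = sum(g$elem %in% c("F", "Cl", "Br", "I")),
      frac_ring = mean(g$ring_atom),
      n_rotatable = n_rot,
      max_degree = max(g$degree, 0),
      n_multiple_bonds = if (nb) sum(g$bonds[, 3] > 1) else 0)
  }, numeric(12)))
  rownames(out) <- mols$id
  out
}

#' Train a fingerprint baseline classifier
#'
#' Gradient-boosted trees (xgboost) or an RBF support vector machine
#' (e1071) over 2048-bit Morgan fingerprints.  Both emit probabilities:
#' xgboost directly, the SVM via Platt scaling (a strictly monotone map
#' of the decision margin, so ranking metrics are unaffected).
#'
#' @param dataset A `labeled_dataset`.
#' @param kind `"gbm_fingerprint"` or `"svm_fingerprint"`.
#' @param config A [model_config()]; `seed` and (for the gbm)
#'   `epochs` (boosting rounds) are honored.
#' @param radius,n_bits Fingerprint parameters.
#' @return A `baseline_model`.
#' @export
train_baseline <- function(dataset, kind = c("gbm_fingerprint", "svm_fingerprint"),
                           config = model_config(variant = kind),
                           radius = 2L, n_bits = 2048L) {
  kind <- match.arg(kind)
  y <- dataset$labels[dataset$molecules$id]
  if (length(unique(y)) < 2) .stopf("degenerate labels: training set has a single class")
  X <- .fp_matrix(dataset$molecules, radius, n_bits)
  if (kind == "gbm_fingerprint") {
    set.seed(config$seed)
    dtrain <- xgboost::xgb.DMatrix(X, label = as.numeric(y))
    fit <- xgboost::xgb.train(params = list(objective = "binary:logistic",
                                            max_depth = 4, eta = 0.2,
                                            nthread = 1, seed = config$seed),
                              data = dtrain, nrounds = max(10L, config$epochs),
                              verbose = 0)
  } else {
    set.seed(config$seed)
    fit <- e1071::svm(x = X, y = factor(y, levels = c(0, 1)),
                      kernel = "radial", probability = TRUE, scale = FALSE)
  }
  structure(list(kind = kind, fit = fit, radius = radius, n_bits = n_bits),
            class = "baseline_model")
}

.fp_matrix <- function(mols, radius = 2L, n_bits = 2048L) {
  fps <- morgan_fingerprint(mols$canonical_smiles, radius, n_bits, ids = mols$id)
  as.matrix(Matrix::sparseMatrix(
    i = rep(seq_along(fps), vapply(fps, function(f) length(f$bits), 0L)),
    j = unlist(lapply(fps, function(f) f$bits)) + 1L,
    x = 1, dims = c(length(fps), n_bits),
    dimnames = list(mols$id, NULL)))
}

#' @rdname train_baseline
#' @param object A `baseline_model`.
#' @param mols Molecule table to score.
#' @param ... Unused.
#' @export
predict.baseline_model <- function(object, mols, ...) {
  X <- .fp_matrix(mols, object$radius, object$n_bits)
  if (object$kind == "gbm_fingerprint") {
    p <- predict(object$fit, xgboost::xgb.DMatrix(X))
  } else {
    pr <- predict(object$fit, X, probability = TRUE)
    p <- attr(pr, "probabilities")[, "1"]
  }
  stats::setNames(as.numeric(p), mols$id)
}
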