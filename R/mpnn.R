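## Directed-bond message-passing neural network (D-MPNN) for molecular
## property prediction, with optional auxiliary feature blocks
## concatenated to the learned molecule vector before the feed-forward
## head.  Forward pass, backpropagation and the Adam optimizer are
## implemented with dense weight matrices and sparse (Matrix)
## bond/atom/molecule aggregation, so training is deterministic for a
## fixed seed.

.ATOM_ELEMS <- c("C", "N", "O", "S", "F", "Cl", "Br", "I", "P")

.atom_features <- function(g) {
  n <- length(g$elem)
  fe <- matrix(0, n, length(.ATOM_ELEMS) + 1L)
  ei <- match(g$elem, .ATOM_ELEMS)
  ei[is.na(ei)] <- length(.ATOM_ELEMS) + 1L
  fe[cbind(seq_len(n), ei)] <- 1
  fd <- matrix(0, n, 5L)
  fd[cbind(seq_len(n), pmin(g$degree, 4L) + 1L)] <- 1
  cbind(fe, fd, ring = as.numeric(g$ring_atom))
}

.bond_features <- function(order, in_ring) {
  fb <- matrix(0, length(order), 4L)
  fb[cbind(seq_along(order), pmin(order, 3L))] <- 1
  fb[, 4] <- as.numeric(in_ring)
  fb
}

.N_ATOM_F <- length(.ATOM_ELEMS) + 1L + 5L + 1L   # element + degree + ring
.N_BOND_F <- 4L

# Assemble the batch tensors for a list of molecule graphs: atom features
# Xa, directed-bond inputs Xb = [source atom features, bond features],
# bond-to-bond aggregation A (incoming minus reverse), atom-from-bond
# incidence T, molecule pooling P, and per-molecule index bookkeeping.
.graph_batch <- function(graphs) {
  n_atoms <- vapply(graphs, function(g) length(g$elem), 0L)
  n_bonds <- vapply(graphs, function(g) 2L * nrow(g$bonds), 0L)
  atom_off <- cumsum(c(0L, n_atoms))
  bond_off <- cumsum(c(0L, n_bonds))
  A_tot <- sum(n_atoms); B_tot <- sum(n_bonds); M <- length(graphs)
  Xa <- matrix(0, A_tot, .N_ATOM_F)
  src <- tgt <- rev_of <- integer(B_tot)
  border <- numeric(B_tot); bring <- logical(B_tot)
  for (m in seq_len(M)) {
    g <- graphs[[m]]
    Xa[atom_off[m] + seq_len(n_atoms[m]), ] <- .atom_features(g)
    nb <- nrow(g$bonds)
    if (nb) {
      e <- bond_off[m] + seq_len(2L * nb)
      a <- g$bonds[, 1] + atom_off[m]; b <- g$bonds[, 2] + atom_off[m]
      src[e] <- as.integer(rbind(a, b)); tgt[e] <- as.integer(rbind(b, a))
      o <- rep(g$bonds[, 3], each = 2L); rg <- rep(g$ring_bond, each = 2L)
      border[e] <- o; bring[e] <- rg
      rev_of[e] <- as.integer(rbind(e[c(FALSE, TRUE)], e[c(TRUE, FALSE)]))
    }
  }
  Xb <- cbind(Xa[src, , drop = FALSE], .bond_features(border, bring))
  # A[e, f] = 1 when f feeds e: target(f) == source(e), f != reverse(e)
  by_target <- split(seq_len(B_tot), factor(tgt, levels = seq_len(A_tot)))
  ai <- unlist(lapply(seq_len(B_tot), function(e) {
    f <- by_target[[src[e]]]
    f[f != rev_of[e]]
  }))
  ei <- rep(seq_len(B_tot), vapply(seq_len(B_tot), function(e) {
    f <- by_target[[src[e]]]
    sum(f != rev_of[e])
  }, 0L))
  A <- Matrix::sparseMatrix(i = ei, j = ai, x = 1, dims = c(B_tot, B_tot))
  T_ <- Matrix::sparseMatrix(i = tgt, j = seq_len(B_tot), x = 1, dims = c(A_tot, B_tot))
  P <- Matrix::sparseMatrix(i = rep(seq_len(M), n_atoms),
                            j = seq_len(A_tot), x = 1, dims = c(M, A_tot))
  list(Xa = Xa, Xb = Xb, A = A, T = T_, P = P, M = M,
       n_atoms = n_atoms, n_bonds = n_bonds)
}

#' Model configuration
#'
#' Hyperparameters for the message-passing classifier and the
#' fingerprint baselines.  Network defaults follow common D-MPNN
#' conventions (hidden 300, depth 3, 2 feed-forward layers, 30 epochs);
#' tests and desk-scale runs use smaller settings.
#'
#' @param variant `"mpnn"`, `"gbm_fingerprint"` or `"svm_fingerprint"`.
#' @param aux_blocks Subset of `c("dti", "ddi", "physchem")`; empty means
#'   structure only.
#' @param hidden_dim,message_depth,ffn_layers Network shape.
#' @param epochs,learning_rate,batch_size Adam schedule.
#' @param seed RNG seed (initialization and epoch shuffling).
#' @return A `model_config` list.
#' @export
model_config <- function(variant = c("mpnn", "gbm_fingerprint", "svm_fingerprint"),
                         aux_blocks = character(0), hidden_dim = 300L,
                         message_depth = 3L, ffn_layers = 2L, epochs = 30L,
                         learning_rate = 1e-3, batch_size = 50L, seed = 1L) {
  variant <- match.arg(variant)
  bad <- setdiff(aux_blocks, c("dti", "ddi", "physchem"))
  if (length(bad)) .stopf("unknown aux block: %s", bad[1])
  structure(list(variant = variant, aux_blocks = aux_blocks,
                 hidden_dim = as.integer(hidden_dim),
                 message_depth = as.integer(message_depth),
                 ffn_layers = as.integer(ffn_layers), epochs = as.integer(epochs),
                 learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Assemble the auxiliary feature matrix for a set of molecules
#'
#' Pulls the requested blocks (`dti`, `ddi` from a [build_feature_table()]
#' result; `physchem` computed from structure) into one molecules x
#' features matrix, rows named by id.
#'
#' @param mols Molecule table.
#' @param blocks Character subset of `c("dti", "ddi", "physchem")`.
#' @param feature_table A `feature_table`, required for dti/ddi blocks.
#' @return Numeric matrix (0 columns when `blocks` is empty).
#' @export
aux_matrix <- function(mols, blocks, feature_table = NULL) {
  out <- matrix(numeric(0), nrow(mols), 0, dimnames = list(mols$id, NULL))
  for (b in blocks) {
    if (b %in% c("dti", "ddi")) {
      if (is.null(feature_table)) .stopf("feature_table required for block %s", b)
      cols <- grep(paste0("^", b, "_"), colnames(feature_table$features))
      miss <- setdiff(mols$id, rownames(feature_table$features))
      if (length(miss)) .stopf("feature table missing rows for %s", miss[1])
      out <- cbind(out, feature_table$features[mols$id, cols, drop = FALSE])
    } else {
      out <- cbind(out, physchem_descriptors(mols))
    }
  }
  out
}

.init_weights <- function(fa, fb, h, aux, ffn_layers) {
  gl <- function(nin, nout) matrix(rnorm(nin * nout, sd = sqrt(2 / (nin + nout))), nin, nout)
  w <- list(Wi = gl(fa + fb, h), bi = numeric(h),
            Wm = gl(h, h),
            Wa = gl(fa + h, h), ba = numeric(h))
  din <- h + aux
  for (l in seq_len(ffn_layers)) {
    dout <- if (l == ffn_layers) 1L else h
    w[[paste0("Wf", l)]] <- gl(din, dout)
    w[[paste0("bf", l)]] <- numeric(dout)
    din <- dout
  }
  w
}

# Forward pass; returns probabilities and, when requested, every cached
# intermediate needed for backpropagation.
.mpnn_forward <- function(w, gb, aux, depth, ffn_layers, keep = FALSE) {
  S0 <- sweep(gb$Xb %*% w$Wi, 2, w$bi, "+")
  H0 <- pmax(S0, 0)
  H <- H0
  masks <- list(); AHs <- list()
  if (depth >= 1) for (t in seq_len(depth)) {
    AH <- as.matrix(gb$A %*% H)
    St <- H0 + AH %*% w$Wm
    H <- pmax(St, 0)
    if (keep) { masks[[t]] <- St > 0; AHs[[t]] <- AH }
  }
  Mv <- as.matrix(gb$T %*% H)
  Sa <- sweep(cbind(gb$Xa, Mv) %*% w$Wa, 2, w$ba, "+")
  Ha <- pmax(Sa, 0)
  G <- as.matrix(gb$P %*% Ha)
  Z <- cbind(G, aux)
  fs <- list(); fin <- Z
  for (l in seq_len(ffn_layers)) {
    Sl <- sweep(fin %*% w[[paste0("Wf", l)]], 2, w[[paste0("bf", l)]], "+")
    out <- if (l == ffn_layers) Sl else pmax(Sl, 0)
    if (keep) fs[[l]] <- list(input = fin, S = Sl)
    fin <- out
  }
  p <- .sigmoid(as.numeric(fin))
  if (!keep) return(list(p = p))
  list(p = p, S0 = S0, masks = masks, AHs = AHs, Mv = Mv, Sa = Sa, Ha = Ha,
       Z = Z, fs = fs)
}

.mpnn_backward <- function(w, gb, aux, y, fw, depth, ffn_layers) {
  Mn <- length(y)
  dlogit <- matrix((fw$p - y) / Mn, ncol = 1)
  gr <- list()
  delta <- dlogit
  for (l in rev(seq_len(ffn_layers))) {
    cache <- fw$fs[[l]]
    dS <- if (l == ffn_layers) delta else delta * (cache$S > 0)
    gr[[paste0("Wf", l)]] <- crossprod(cache$input, dS)
    gr[[paste0("bf", l)]] <- colSums(dS)
    delta <- dS %*% t(w[[paste0("Wf", l)]])
  }
  h <- ncol(w$Wm)
  dG <- delta[, seq_len(h), drop = FALSE]
  dHa <- as.matrix(Matrix::crossprod(gb$P, dG))
  dSa <- dHa * (fw$Sa > 0)
  gr$Wa <- crossprod(cbind(gb$Xa, fw$Mv), dSa)
  gr$ba <- colSums(dSa)
  dMv <- dSa %*% t(w$Wa[.N_ATOM_F + seq_len(h), , drop = FALSE])
  dH <- as.matrix(Matrix::crossprod(gb$T, dMv))   # grad wrt H_depth
  dWm <- matrix(0, h, h)
  dH0 <- matrix(0, nrow(dH), h)
  if (depth >= 1) {
    for (t in rev(seq_len(depth))) {
      dSt <- dH * fw$masks[[t]]
      dWm <- dWm + crossprod(fw$AHs[[t]], dSt)
      dH0 <- dH0 + dSt                              # skip connection to H0
      dH <- as.matrix(Matrix::crossprod(gb$A, dSt %*% t(w$Wm)))
    }
    dH0 <- dH0 + dH                                 # message path into H0
  } else {
    dH0 <- dH
  }
  dS0 <- dH0 * (fw$S0 > 0)
  gr$Wm <- dWm
  gr$Wi <- crossprod(gb$Xb, dS0)
  gr$bi <- colSums(dS0)
  gr
}

.adam_state <- function(w) lapply(w, function(x) list(m = x * 0, v = x * 0))

.adam_step <- function(w, gr, st, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  for (nm in names(gr)) {
    g <- gr[[nm]]
    st[[nm]]$m <- b1 * st[[nm]]$m + (1 - b1) * g
    st[[nm]]$v <- b2 * st[[nm]]$v + (1 - b2) * g^2
    mh <- st[[nm]]$m / (1 - b1^t)
    vh <- st[[nm]]$v / (1 - b2^t)
    w[[nm]] <- w[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(w = w, st = st)
}

#' Train a directed-bond message-passing classifier
#'
#' Bond-level messages are initialized from source-atom and bond
#' features, refined for `message_depth` rounds of neighbor aggregation
#' (excluding the reverse bond), read out per atom and summed to a
#' molecule vector, concatenated with the selected auxiliary blocks
#' (z-scored on the training set) and passed through a feed-forward head
#' with sigmoid output.  Trained with Adam on binary cross-entropy.
#'
#' @param dataset A `labeled_dataset` containing both classes.
#' @param features Optional `feature_table` (required when
#'   `config$aux_blocks` mentions dti/ddi).
#' @param config A [model_config()] with `variant = "mpnn"`.
#' @return An `mpnn_model`.
#' @export
train_mpnn <- function(dataset, features = NULL, config = model_config()) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  y <- dataset$labels[dataset$molecules$id]
  if (length(unique(y)) < 2) .stopf("degenerate labels: training set has a single class")
  aux <- aux_matrix(dataset$molecules, config$aux_blocks, features)
  aux_mean <- if (ncol(aux)) colMeans(aux) else numeric(0)
  aux_sd <- if (ncol(aux)) apply(aux, 2, stats::sd) else numeric(0)
  aux_sd[aux_sd < 1e-12] <- 1
  auxz <- if (ncol(aux)) sweep(sweep(aux, 2, aux_mean), 2, aux_sd, "/") else aux
  graphs <- .mol_graphs(dataset$molecules$canonical_smiles)
  set.seed(config$seed)
  w <- .init_weights(.N_ATOM_F, .N_BOND_F, config$hidden_dim, ncol(aux), config$ffn_layers)
  st <- .adam_state(w)
  n <- length(y)
  step <- 0L
  for (ep in seq_len(config$epochs)) {
    ordr <- sample.int(n)
    starts <- seq(1, n, by = config$batch_size)
    for (s in starts) {
      idx <- ordr[s:min(s + config$batch_size - 1, n)]
      gb <- .graph_batch(graphs[idx])
      fw <- .mpnn_forward(w, gb, auxz[idx, , drop = FALSE],
                          config$message_depth, config$ffn_layers, keep = TRUE)
      gr <- .mpnn_backward(w, gb, auxz[idx, , drop = FALSE], as.numeric(y[idx]),
                           fw, config$message_depth, config$ffn_layers)
      step <- step + 1L
      up <- .adam_step(w, gr, st, config$learning_rate, step)
      w <- up$w; st <- up$st
    }
  }
  structure(list(weights = w, config = config, aux_mean = aux_mean, aux_sd = aux_sd,
                 n_aux = ncol(aux)),
            class = "mpnn_model")
}

#' Predict activity probabilities with a trained MPNN
#'
#' @param object An `mpnn_model`.
#' @param mols Molecule table to score.
#' @param features Optional `feature_table` for auxiliary blocks.
#' @param ... Unused.
#' @return Named numeric scores in `[0, 1]`; unparseable molecules get
#'   `NA` with a warning.
#' @export
predict.mpnn_model <- function(object, mols, features = NULL, ...) {
  ok <- vapply(mols$smiles, function(s)
    !inherits(try(canonicalize(s), silent = TRUE), "try-error"), logical(1))
  if (any(!ok)) .warnf("%d molecules could not be parsed; scores set to NA", sum(!ok))
  out <- stats::setNames(rep(NA_real_, nrow(mols)), mols$id)
  mols_ok <- mols[ok, , drop = FALSE]
  if (!nrow(mols_ok)) return(out)
  aux <- aux_matrix(mols_ok, object$config$aux_blocks, features)
  auxz <- if (ncol(aux)) sweep(sweep(aux, 2, object$aux_mean), 2, object$aux_sd, "/") else aux
  graphs <- .mol_graphs(mols_ok$canonical_smiles)
  gb <- .graph_batch(graphs)
  fw <- .mpnn_forward(object$weights, gb, auxz, object$config$message_depth,
                      object$config$ffn_layers)
  out[mols_ok$id] <- fw$p
  out
}

#' Train an ensemble of message-passing models
#'
#' Members share the configuration but use seeds `seed, seed + 1, ...`;
#' the ensemble prediction is the arithmetic mean of member
#' probabilities.
#'
#' @inheritParams train_mpnn
#' @param n_members Ensemble size (default 2).
#' @return An `mpnn_ensemble`.
#' @export
train_ensemble <- function(dataset, features = NULL, config = model_config(),
                           n_members = 2L) {
  seeds <- config$seed + seq_len(n_members) - 1L
  members <- lapply(seeds, function(s) {
    cfg <- config; cfg$seed <- as.integer(s)
    train_mpnn(dataset, features, cfg)
  })
  structure(list(members = members, config = config, member_seeds = seeds),
            class = "mpnn_ensemble")
}

#' @rdname train_ensemble
#' @param object An `mpnn_ensemble`.
#' @param mols Molecule table to score.
#' @param ... Unused.
#' @export
predict.mpnn_ensemble <- function(object, mols, features = NULL, ...) {
  preds <- lapply(object$members, predict, mols = mols, features = features)
  Reduce(`+`, preds) / length(preds)
}
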