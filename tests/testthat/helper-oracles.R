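# Independent brute-force oracles used to validate the metric suite and
# neighbor search, plus small fixture builders.

# AUC by exhaustive pairwise concordance, ties half credit.
auc_brute <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# AUPR by a full sweep over unique thresholds, step summation.
aupr_brute <- function(labels, scores) {
  ths <- sort(unique(scores), decreasing = TRUE)
  np <- sum(labels == 1)
  prev_r <- 0; ap <- 0
  for (t in ths) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    prec <- tp / sum(pred)
    rec <- tp / np
    ap <- ap + (rec - prev_r) * prec
    prev_r <- rec
  }
  ap
}

# Accuracy / kappa / MCC from explicit confusion counts.
confusion_brute <- function(labels, scores, threshold = 0.5) {
  pred <- as.integer(scores >= threshold)
  TP <- sum(pred == 1 & labels == 1); FP <- sum(pred == 1 & labels == 0)
  TN <- sum(pred == 0 & labels == 0); FN <- sum(pred == 0 & labels == 1)
  n <- length(labels)
  acc <- (TP + TN) / n
  pe <- ((TP + FP) * (TP + FN) + (TN + FN) * (TN + FP)) / n^2
  kap <- if (pe == 1) 0 else (acc - pe) / (1 - pe)
  den <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  mcc <- if (den == 0) 0 else (TP * TN - FP * FN) / sqrt(den)
  list(accuracy = acc, kappa = kap, mcc = mcc)
}

# Direct fingerprint construction for similarity property tests.
make_fp <- function(bits, n_bits = 64L, id = "x") {
  structure(list(bits = sort(unique(as.integer(bits))), n_bits = as.integer(n_bits),
                 radius = 2L, molecule_id = id), class = "fingerprint")
}

# A reusable small molecule set with shared scaffolds and side-chains.
fixture_molecules <- function() {
  molecule_table(
    paste0("m", 1:10),
    c("c1ccccc1", "Cc1ccccc1", "CCc1ccccc1", "Oc1ccccc1",
      "c1ccncc1", "Cc1ccncc1",
      "c1ccc2ccccc2c1", "Cc1ccc2ccccc2c1",
      "CCO", "CC(C)O"))
}

# Labeled dataset whose label is presence of the planted nitro motif.
motif_dataset <- function(n = 200, n_templates = 20, seed = 4, motif_rate = 0.35) {
  mols <- generate_molecules(n, n_templates, seed = seed, motif_rate = motif_rate)
  meta <- attr(mols, "meta")
  structure(list(molecules = mols,
                 labels = stats::setNames(as.integer(meta$motif), mols$id),
                 provenance = stats::setNames(rep("motif", n), mols$id)),
            class = "labeled_dataset")
}

# Planted two-community graph as an interaction matrix + community ids.
planted_ddi <- function(n = 200, p_in = 0.3, p_out = 0.02, seed = 42) {
  set.seed(seed)
  comm <- rep(1:2, each = n / 2)
  prs <- t(combn(n, 2))
  pe <- ifelse(comm[prs[, 1]] == comm[prs[, 2]], p_in, p_out)
  keep <- runif(nrow(prs)) < pe
  ids <- sprintf("g%03d", seq_len(n))
  list(ddi = interaction_matrix(ids, ids,
                                cbind(ids[prs[keep, 1]], ids[prs[keep, 2]]), "DDI"),
       ids = ids, comm = comm, pairs = prs, edge = keep)
}

# Six-drug toy catalogue: 2 positives, 1 approved trial drug, 1 approved
# drug identical to a positive, 2 clean approved drugs.
toy_catalogue <- function() {
  mols <- molecule_table(paste0("d", 1:6),
                         c("c1ccc2ccccc2c1",
                           "O=[N+]([O-])c1ccccc1",
                           "c1ccncc1",
                           "C1=CC2=CC=CC=C2C=C1",   # same molecule as d1
                           "CCO",
                           "CC(C)CC1CCC(C)CC1"))
  catalogue_table(mols,
                  approved = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
                  in_cancer_trial = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
                  known_anticancer = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
}
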