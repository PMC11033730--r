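## Synthetic benchmark generator: template-assembled molecules, planted
## drug-target and drug-drug interaction structure, and labels whose
## signal is split between a structural motif, DTI class membership and
## DDI community membership.  Every downstream module is testable
## against the recorded ground truth without licensed databases.

# Ring-system templates are assembled from single-ring cores and
# (core x linker x second ring) combinations; each template carries one
# substitution site for the side-chain substituent, so molecules built
# from the same template share a Bemis-Murcko scaffold while differing
# in side chains.
.SINGLE_CORES <- c("c1ccc(%s)cc1",          # benzene
                   "c1ccc(%s)nc1",          # pyridine
                   "c1ccc2cc(%s)ccc2c1",    # naphthalene
                   "C1CCC(%s)CC1",          # cyclohexane
                   "c1cc(%s)sc1",           # thiophene
                   "c1cc(%s)oc1",           # furan
                   "C1CCN(%s)CC1",          # piperidine (N-substituted)
                   "C1CCC(%s)C1")           # cyclopentane

.DOUBLE_CORES <- c("c1cc(%s)ccc1%s",        # benzene, two sites
                   "C1CC(%s)CCC1%s",        # cyclohexane
                   "c1sc(%s)cc1%s")         # thiophene

.SECOND_RINGS <- c("c2ccccc2", "c2ccncc2", "C2CCCCC2", "c2ccc3ccccc3c2",
                   "C2CCNCC2", "c2cccs2")

.LINKERS <- c("", "C", "CC", "O", "N", "OC")

.MOTIF_SUBSTITUENT <- "[N+](=O)[O-]"        # planted structural motif (nitro)

.PLAIN_SUBSTITUENTS <- c("C", "CC", "CCC", "O", "OC", "N", "Cl", "F",
                         "C(=O)O", "C#N", "S")

.template_env <- new.env(parent = emptyenv())

# Enumerate candidate templates in a fixed order, keep those that yield
# valid molecules with a probe substituent and pairwise-distinct
# scaffolds.  Cached per session.
.template_catalog <- function() {
  if (!is.null(.template_env$catalog)) return(.template_env$catalog)
  combos <- expand.grid(core = .DOUBLE_CORES, linker = .LINKERS,
                        ring2 = .SECOND_RINGS, stringsAsFactors = FALSE)
  cand <- c(.SINGLE_CORES,
            vapply(seq_len(nrow(combos)), function(k)
              sub("%s", paste0(combos$linker[k], combos$ring2[k]),
                  combos$core[k], fixed = TRUE),
              "", USE.NAMES = FALSE))
  probe <- vapply(cand, function(tp) sprintf(tp, "C"), "", USE.NAMES = FALSE)
  ok <- vapply(probe, function(s)
    !inherits(try(canonicalize(s), silent = TRUE), "try-error"), logical(1))
  cand <- cand[ok]; probe <- probe[ok]
  scaff <- bemis_murcko_scaffold(probe)
  keep <- !duplicated(scaff) & nzchar(scaff)
  .template_env$catalog <- cand[keep]
  .template_env$catalog
}

#' Benchmark configuration
#'
#' Generation parameters for the synthetic benchmark.  Defaults describe
#' the study conditions exercised by the package's tests: 500 drugs over
#' 60 scaffold templates, a 100-target DTI matrix with 4 latent classes,
#' a 4-community DDI graph, label signal split between a structural
#' motif and DTI/DDI membership, a 1/3 positive rate (echoing a 451:918
#' class balance), 10% label noise and 10% of drugs masked from each
#' interaction matrix to exercise imputation.
#'
#' @param n_drugs,n_targets,n_scaffold_templates Sizes.
#' @param ddi_communities,n_dti_classes Latent group counts; groups 1 and
#'   2 of each are the label-active sets.
#' @param signal_weights Named vector `(structure, dti, ddi)` of logit
#'   weights.
#' @param label_noise Label flip probability in `[0, 0.5)`.
#' @param mask_fraction_dti,mask_fraction_ddi Fraction of drugs withheld
#'   from each matrix.
#' @param positive_rate Target marginal positive rate.
#' @param motif_rate Probability a molecule carries the structural motif
#'   substituent.
#' @param p_dti_hit,p_dti_bg DTI hit probabilities (class-owned targets /
#'   background).
#' @param p_ddi_within,p_ddi_between DDI stochastic-block-model edge
#'   probabilities.
#' @param seed Master seed; all sub-generators derive from it.
#' @return A `benchmark_config` list.
#' @export
benchmark_config <- function(n_drugs = 500L, n_targets = 100L,
                             n_scaffold_templates = 60L,
                             ddi_communities = 4L, n_dti_classes = 4L,
                             signal_weights = c(structure = 6, dti = 7, ddi = 8),
                             label_noise = 0.1,
                             mask_fraction_dti = 0.1, mask_fraction_ddi = 0.1,
                             positive_rate = 1 / 3, motif_rate = 0.25,
                             p_dti_hit = 0.6, p_dti_bg = 0.02,
                             p_ddi_within = 0.25, p_ddi_between = 0.01,
                             seed = 1L) {
  if (label_noise < 0 || label_noise >= 0.5) .stopf("label_noise must be in [0, 0.5)")
  if (mask_fraction_dti < 0 || mask_fraction_dti >= 1 ||
      mask_fraction_ddi < 0 || mask_fraction_ddi >= 1)
    .stopf("mask fractions must be in [0, 1)")
  structure(list(n_drugs = as.integer(n_drugs), n_targets = as.integer(n_targets),
                 n_scaffold_templates = as.integer(n_scaffold_templates),
                 ddi_communities = as.integer(ddi_communities),
                 n_dti_classes = as.integer(n_dti_classes),
                 signal_weights = signal_weights, label_noise = label_noise,
                 mask_fraction_dti = mask_fraction_dti,
                 mask_fraction_ddi = mask_fraction_ddi,
                 positive_rate = positive_rate, motif_rate = motif_rate,
                 p_dti_hit = p_dti_hit, p_dti_bg = p_dti_bg,
                 p_ddi_within = p_ddi_within, p_ddi_between = p_ddi_between,
                 seed = as.integer(seed)),
            class = "benchmark_config")
}

#' Generate template-assembled molecules
#'
#' Builds `n` valid SMILES by attaching one substituent from a fixed
#' vocabulary to one of `n_templates` ring-system templates.  Every
#' template is used at least once, so at least `n_templates` distinct
#' Bemis-Murcko scaffolds appear.  Deterministic for a fixed seed.
#'
#' @param n Number of molecules.
#' @param n_templates Number of ring-system templates (>= 2).
#' @param seed RNG seed.
#' @param motif_rate Probability of drawing the motif substituent.
#' @return Molecule table with a `meta` attribute recording
#'   `template_idx`, `substituent` and the `motif` indicator.
#' @export
generate_molecules <- function(n, n_templates = 60L, seed = 1L, motif_rate = 0.25) {
  if (n < n_templates || n_templates < 2) .stopf("need n >= n_templates >= 2")
  catalog <- .template_catalog()
  if (n_templates > length(catalog))
    .stopf("only %d distinct templates available", length(catalog))
  templates <- catalog[seq_len(n_templates)]
  set.seed(seed)
  tidx <- c(seq_len(n_templates), sample.int(n_templates, n - n_templates, replace = TRUE))
  tidx <- tidx[sample.int(n)]
  subs <- ifelse(runif(n) < motif_rate, .MOTIF_SUBSTITUENT,
                 sample(.PLAIN_SUBSTITUENTS, n, replace = TRUE))
  smiles <- sprintf(templates[tidx], subs)
  # validity contract: every assembled SMILES must parse; retry with a
  # plain substituent a bounded number of times
  for (attempt in 1:5) {
    bad <- vapply(smiles, function(s)
      inherits(try(canonicalize(s), silent = TRUE), "try-error"), logical(1))
    if (!any(bad)) break
    subs[bad] <- sample(.PLAIN_SUBSTITUENTS, sum(bad), replace = TRUE)
    smiles[bad] <- sprintf(templates[tidx[bad]], subs[bad])
  }
  if (any(bad)) .stopf("could not assemble a valid molecule for template %d", tidx[bad][1])
  ids <- sprintf("D%05d", seq_len(n))
  mols <- molecule_table(ids, smiles)
  attr(mols, "meta") <- data.frame(id = ids, template_idx = tidx, substituent = subs,
                                   motif = subs == .MOTIF_SUBSTITUENT,
                                   stringsAsFactors = FALSE)
  mols
}

#' Generate planted DTI and DDI matrices
#'
#' Each drug gets a latent DTI class (class-owned target columns hit
#' with `p_dti_hit`, background `p_dti_bg`) and a latent DDI community
#' (stochastic block model, `p_ddi_within` / `p_ddi_between`).  A
#' fraction of drugs is withheld from each matrix to exercise
#' imputation; the masked ids are recorded.
#'
#' @param mols Molecule table from [generate_molecules()].
#' @param config A [benchmark_config()].
#' @param seed RNG seed (defaults to a sub-seed of `config$seed`).
#' @return List `dti`, `ddi` (interaction matrices) and `ground_truth`
#'   (`dti_class`, `ddi_community`, `motif`, masked id lists).
#' @export
generate_interactions <- function(mols, config, seed = NULL) {
  n <- nrow(mols)
  if (is.null(seed)) seed <- .derive_seeds(config$seed, 3L)[2]
  set.seed(seed)
  ids <- mols$id
  kC <- config$n_dti_classes
  dti_class <- sample.int(kC, n, replace = TRUE)
  block <- max(1L, config$n_targets %/% (kC + 1L))
  owned <- lapply(seq_len(kC), function(c) ((c - 1L) * block + 1L):(c * block))
  P <- matrix(config$p_dti_bg, n, config$n_targets)
  for (c in seq_len(kC)) P[dti_class == c, owned[[c]]] <- config$p_dti_hit
  hits <- which(matrix(runif(n * config$n_targets), n) < P, arr.ind = TRUE)
  target_ids <- sprintf("T%04d", seq_len(config$n_targets))
  ddi_comm <- sample.int(config$ddi_communities, n, replace = TRUE)
  prs <- t(utils::combn(n, 2L))
  pe <- ifelse(ddi_comm[prs[, 1]] == ddi_comm[prs[, 2]],
               config$p_ddi_within, config$p_ddi_between)
  keep <- runif(nrow(prs)) < pe
  edges <- prs[keep, , drop = FALSE]
  mask_dti <- sort(sample(ids, floor(config$mask_fraction_dti * n)))
  mask_ddi <- sort(sample(ids, floor(config$mask_fraction_ddi * n)))
  dti_rows <- setdiff(ids, mask_dti)
  hits_keep <- hits[!(ids[hits[, 1]] %in% mask_dti), , drop = FALSE]
  dti <- interaction_matrix(dti_rows, target_ids,
                            cbind(ids[hits_keep[, 1]], target_ids[hits_keep[, 2]]),
                            kind = "DTI")
  ddi_ids <- setdiff(ids, mask_ddi)
  ek <- !(ids[edges[, 1]] %in% mask_ddi) & !(ids[edges[, 2]] %in% mask_ddi)
  ddi <- interaction_matrix(ddi_ids, ddi_ids,
                            cbind(ids[edges[ek, 1]], ids[edges[ek, 2]]),
                            kind = "DDI")
  meta <- attr(mols, "meta")
  gt <- list(ids = ids,
             dti_class = stats::setNames(dti_class, ids),
             ddi_community = stats::setNames(ddi_comm, ids),
             motif = stats::setNames(meta$motif, ids),
             masked_dti_ids = mask_dti, masked_ddi_ids = mask_ddi,
             active_dti_classes = c(1L, 2L), active_ddi_communities = c(1L, 2L))
  list(dti = dti, ddi = ddi, ground_truth = gt)
}

# Latent logit and oracle probability per drug; the intercept is chosen
# so the mean logistic probability hits the configured positive rate.
.oracle_logits <- function(ground_truth, signal_weights, positive_rate) {
  s <- as.numeric(ground_truth$motif)
  t <- as.numeric(ground_truth$dti_class %in% ground_truth$active_dti_classes)
  d <- as.numeric(ground_truth$ddi_community %in% ground_truth$active_ddi_communities)
  raw <- signal_weights[["structure"]] * s + signal_weights[["dti"]] * t +
    signal_weights[["ddi"]] * d
  c0 <- uniroot(function(c) mean(plogis(raw + c)) - positive_rate,
                c(-50, 50))$root
  stats::setNames(raw + c0, ground_truth$ids)
}

#' Oracle scores from the planted ground truth
#'
#' The logistic probability each drug's label was sampled from (before
#' noise); the reference any trained model is compared against.
#'
#' @param ground_truth From [generate_interactions()].
#' @param signal_weights,positive_rate As in [benchmark_config()].
#' @return Named probabilities.
#' @export
oracle_scores <- function(ground_truth, signal_weights = c(structure = 6, dti = 7, ddi = 8),
                          positive_rate = 1 / 3) {
  plogis(.oracle_logits(ground_truth, signal_weights, positive_rate))
}

#' Sample labels from the planted signal
#'
#' Per-drug logit = `w_structure * motif + w_dti * active-DTI-class +
#' w_ddi * active-DDI-community + intercept`, the intercept set to hit
#' `positive_rate`; labels are Bernoulli draws from the logistic
#' probability, then flipped with probability `label_noise`.
#'
#' @inheritParams oracle_scores
#' @param label_noise Flip probability.
#' @param seed RNG seed.
#' @return Named 0/1 integer vector.
#' @export
generate_labels <- function(ground_truth, signal_weights = c(structure = 6, dti = 7, ddi = 8),
                            label_noise = 0.1, seed = 1L, positive_rate = 1 / 3) {
  p <- plogis(.oracle_logits(ground_truth, signal_weights, positive_rate))
  set.seed(seed)
  y <- as.integer(runif(length(p)) < p)
  flip <- runif(length(p)) < label_noise
  y[flip] <- 1L - y[flip]
  stats::setNames(y, names(p))
}

#' Generate a full benchmark bundle
#'
#' Composes molecule, interaction and label generation from one master
#' seed.  The catalogue marks every labeled-positive drug as known
#' anti-cancer; a small share of negatives is flagged as cancer-trial
#' drugs so curation filters have work to do.
#'
#' @param config A [benchmark_config()].
#' @return A `benchmark_bundle`: `catalogue`, `dti`, `ddi`, `labels`,
#'   `ground_truth`, `config`.
#' @export
make_benchmark <- function(config = benchmark_config()) {
  seeds <- .derive_seeds(config$seed, 4L)
  mols <- generate_molecules(config$n_drugs, config$n_scaffold_templates,
                             seed = seeds[1], motif_rate = config$motif_rate)
  ia <- generate_interactions(mols, config, seed = seeds[2])
  labels <- generate_labels(ia$ground_truth, config$signal_weights,
                            config$label_noise, seed = seeds[3],
                            positive_rate = config$positive_rate)
  set.seed(seeds[4])
  trial <- labels == 0 & runif(length(labels)) < 0.05
  catalogue <- catalogue_table(mols, approved = TRUE,
                               in_cancer_trial = unname(trial[mols$id]),
                               known_anticancer = unname(labels[mols$id] == 1))
  attr(catalogue, "meta") <- attr(mols, "meta")
  structure(list(catalogue = catalogue, dti = ia$dti, ddi = ia$ddi,
                 labels = labels, ground_truth = ia$ground_truth, config = config),
            class = "benchmark_bundle")
}

#' Labeled dataset straight from a benchmark bundle
#'
#' Uses the generator's labels for all drugs (no curation filtering);
#' the input for training and evaluation runs.
#'
#' @param bundle A `benchmark_bundle`.
#' @return A `labeled_dataset`.
#' @export
benchmark_dataset <- function(bundle) {
  mols <- bundle$catalogue[, c("id", "smiles", "canonical_smiles", "name")]
  structure(list(molecules = mols, labels = bundle$labels[mols$id],
                 provenance = stats::setNames(rep("synthetic", nrow(mols)), mols$id)),
            class = "labeled_dataset")
}

#' Write a benchmark bundle to a directory
#'
#' Emits the pipeline's standard file formats: `catalogue.csv`,
#' `dti.tsv` / `ddi.tsv` (+ id sidecars), `labels.csv`.
#'
#' @param bundle A `benchmark_bundle`.
#' @param dir Output directory (created if missing).
#' @export
write_benchmark <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cat_df <- data.frame(id = bundle$catalogue$id, smiles = bundle$catalogue$smiles,
                       approved = as.integer(bundle$catalogue$approved),
                       in_cancer_trial = as.integer(bundle$catalogue$in_cancer_trial),
                       known_anticancer = as.integer(bundle$catalogue$known_anticancer))
  write.csv(cat_df, file.path(dir, "catalogue.csv"), row.names = FALSE, quote = FALSE)
  write_interactions(bundle$dti, file.path(dir, "dti.tsv"))
  write_interactions(bundle$ddi, file.path(dir, "ddi.tsv"))
  write.csv(data.frame(id = names(bundle$labels), label = unname(bundle$labels)),
            file.path(dir, "labels.csv"), row.names = FALSE, quote = FALSE)
  invisible(dir)
}
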