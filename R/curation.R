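## Label curation: assemble the positive / negative anti-cancer activity
## dataset from a drug catalogue.  Positives are drugs with documented
## anti-cancer activity; negatives are approved drugs never examined in a
## cancer trial and not chemically similar (Tanimoto on Morgan
## fingerprints) to any cancer-associated drug.

#' Build a drug catalogue table
#'
#' @param mols Molecule table ([molecule_table()]).
#' @param approved,in_cancer_trial,known_anticancer Logical flags per drug.
#' @return Catalogue `data.frame`.
#' @export
catalogue_table <- function(mols, approved, in_cancer_trial, known_anticancer) {
  if (anyDuplicated(mols$id)) {
    dup <- mols$id[duplicated(mols$id)][1]
    .stopf("duplicate catalogue id: %s", dup)
  }
  cbind(mols, data.frame(approved = as.logical(approved),
                         in_cancer_trial = as.logical(in_cancer_trial),
                         known_anticancer = as.logical(known_anticancer)))
}

#' Read a catalogue CSV
#'
#' Columns `id,smiles,approved,in_cancer_trial,known_anticancer` with 0/1
#' flags.  Unparseable SMILES rows are dropped with a warning.
#' @param path CSV path.
#' @export
read_catalogue <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "smiles", "approved", "in_cancer_trial", "known_anticancer")
  if (!all(need %in% names(df))) .stopf("catalogue CSV needs columns %s", paste(need, collapse = ","))
  ok <- vapply(df$smiles, function(s) !inherits(try(canonicalize(s), silent = TRUE), "try-error"),
               logical(1))
  if (any(!ok)) .warnf("dropping %d catalogue rows with unparseable SMILES", sum(!ok))
  df <- df[ok, , drop = FALSE]
  catalogue_table(molecule_table(df$id, df$smiles),
                  df$approved == 1 | df$approved == TRUE,
                  df$in_cancer_trial == 1 | df$in_cancer_trial == TRUE,
                  df$known_anticancer == 1 | df$known_anticancer == TRUE)
}

.check_catalogue <- function(catalogue) {
  if (nrow(catalogue) == 0L) .stopf("catalogue is empty")
  if (anyDuplicated(catalogue$id)) {
    dup <- catalogue$id[duplicated(catalogue$id)][1]
    .stopf("duplicate catalogue id: %s", dup)
  }
}

#' Positive set: drugs with known anti-cancer activity
#'
#' @param catalogue Catalogue table.
#' @return Character vector of ids.
#' @export
assemble_positives <- function(catalogue) {
  .check_catalogue(catalogue)
  sort(catalogue$id[catalogue$known_anticancer])
}

#' Negative set: approved drugs far from any cancer-associated drug
#'
#' Keeps drugs that are approved, lack known anti-cancer activity, were
#' never in a cancer trial, and whose maximal fingerprint similarity to
#' any cancer-associated drug (trial drugs, plus positives when
#' `exclude_positives`) is below `threshold`.
#'
#' @param catalogue Catalogue table.
#' @param threshold Similarity exclusion threshold (default 0.7, the
#'   catalogue similarity tool's default).
#' @param exclude_positives Also screen against known-anti-cancer drugs,
#'   not just trial drugs (default `TRUE`: every positive is
#'   definitionally cancer-associated).
#' @param radius,n_bits Fingerprint parameters.
#' @return Character vector of ids.
#' @export
assemble_negatives <- function(catalogue, threshold = 0.7, exclude_positives = TRUE,
                               radius = 2L, n_bits = 2048L) {
  .check_catalogue(catalogue)
  if (threshold < 0 || threshold > 1) .stopf("threshold must be in [0,1]")
  cand <- catalogue$approved & !catalogue$known_anticancer & !catalogue$in_cancer_trial
  excl <- catalogue$in_cancer_trial | (exclude_positives & catalogue$known_anticancer)
  ids <- catalogue$id[cand]
  if (!length(ids)) return(character(0))
  if (!any(excl)) return(sort(ids))
  fc <- morgan_fingerprint(catalogue$canonical_smiles[cand], radius, n_bits,
                           ids = catalogue$id[cand])
  fe <- morgan_fingerprint(catalogue$canonical_smiles[excl], radius, n_bits,
                           ids = catalogue$id[excl])
  maxsim <- apply(.tanimoto_cross(fc, fe), 1, max)
  sort(ids[maxsim < threshold])
}

#' Assemble the labeled dataset
#'
#' Positives (label 1) and curated negatives (label 0) with per-id
#' provenance tags.  An optional override map (id -> 0/1) is applied last,
#' a reproducible stand-in for manual pharmacologist validation.
#'
#' @inheritParams assemble_negatives
#' @param override Optional named integer vector of forced labels.
#' @return A `labeled_dataset`: list of `molecules` (molecule table),
#'   `labels` (named 0/1 integers) and `provenance` (named tags).
#' @export
build_dataset <- function(catalogue, threshold = 0.7, exclude_positives = TRUE,
                          override = NULL, radius = 2L, n_bits = 2048L) {
  pos <- assemble_positives(catalogue)
  neg <- assemble_negatives(catalogue, threshold, exclude_positives, radius, n_bits)
  if (length(intersect(pos, neg)))
    .stopf("internal consistency: id %s labeled both positive and negative",
           intersect(pos, neg)[1])
  if (!length(pos)) .warnf("catalogue yields zero positive drugs")
  labels <- c(stats::setNames(rep(1L, length(pos)), pos),
              stats::setNames(rep(0L, length(neg)), neg))
  provenance <- c(stats::setNames(rep("known_anticancer", length(pos)), pos),
                  stats::setNames(rep("approved_clean", length(neg)), neg))
  if (!is.null(override)) {
    unknown <- setdiff(names(override), catalogue$id)
    if (length(unknown)) .warnf("override ids not in catalogue ignored: %s", unknown[1])
    ov <- override[names(override) %in% catalogue$id]
    labels[names(ov)] <- as.integer(ov)
    provenance[names(ov)] <- "override"
  }
  mols <- catalogue[match(names(labels), catalogue$id),
                    c("id", "smiles", "canonical_smiles", "name")]
  rownames(mols) <- NULL
  structure(list(molecules = mols, labels = labels, provenance = provenance),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("labeled_dataset: %d molecules (%d positive, %d negative)\n",
              length(x$labels), sum(x$labels == 1), sum(x$labels == 0)))
  invisible(x)
}

#' Write / read a labeled dataset as CSV
#'
#' Columns `id,smiles,label,provenance`.
#' @param dataset A `labeled_dataset`.
#' @param path CSV path.
#' @export
write_dataset <- function(dataset, path) {
  write.csv(data.frame(id = dataset$molecules$id, smiles = dataset$molecules$smiles,
                       label = unname(dataset$labels[dataset$molecules$id]),
                       provenance = unname(dataset$provenance[dataset$molecules$id])),
            path, row.names = FALSE, quote = FALSE)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  mols <- molecule_table(df$id, df$smiles)
  structure(list(molecules = mols,
                 labels = stats::setNames(as.integer(df$label), df$id),
                 provenance = stats::setNames(as.character(df$provenance), df$id)),
            class = "labeled_dataset")
}
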