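## Repeated scaffold-split evaluation across model variants: the
## feature-ablation comparison (structure only vs DTI / DDI / physchem
## blocks vs fingerprint baselines).

.subset_dataset <- function(dataset, ids) {
  structure(list(molecules = dataset$molecules[dataset$molecules$id %in% ids, , drop = FALSE],
                 labels = dataset$labels[ids],
                 provenance = dataset$provenance[ids]),
            class = "labeled_dataset")
}

.train_variant <- function(config, train_ds, features, n_members) {
  if (config$variant == "mpnn") train_ensemble(train_ds, features, config, n_members)
  else train_baseline(train_ds, config$variant, config)
}

.score_variant <- function(model, mols, features) {
  if (inherits(model, "baseline_model")) predict(model, mols)
  else predict(model, mols, features = features)
}

#' Run a feature-ablation evaluation
#'
#' For each repeat a fresh balanced scaffold split is drawn (seed
#' `base_seed + repeat - 1`); every variant is trained on the train
#' partition and scored on test, and the five-metric report is averaged
#' per variant over repeats.
#'
#' @param dataset A `labeled_dataset`.
#' @param features A `feature_table` (or `NULL` when no variant uses
#'   dti/ddi blocks).
#' @param variants Named list of [model_config()]s.
#' @param n_repeats Number of repeated splits (default 3).
#' @param base_seed First split seed.
#' @param fractions Split fractions.
#' @param n_members Ensemble size for mpnn variants (default 2).
#' @return An `ablation_report`: `rows` (variant -> mean metrics),
#'   `raw` (per repeat x variant `metric_report`s), `n_repeats`.
#' @export
run_ablation <- function(dataset, features, variants, n_repeats = 3L,
                         base_seed = 1L, fractions = c(0.8, 0.1, 0.1),
                         n_members = 2L) {
  if (is.null(names(variants)) || any(!nzchar(names(variants))))
    .stopf("variants must be a named list")
  raw <- list()
  for (r in seq_len(n_repeats)) {
    plan <- scaffold_split(dataset, fractions, seed = base_seed + r - 1L)
    train_ds <- .subset_dataset(dataset, split_ids(plan, "train"))
    test_ids <- split_ids(plan, "test")
    test_mols <- dataset$molecules[dataset$molecules$id %in% test_ids, , drop = FALSE]
    for (v in names(variants)) {
      model <- .train_variant(variants[[v]], train_ds, features, n_members)
      scores <- .score_variant(model, test_mols, features)
      raw[[v]][[r]] <- compute_metrics(dataset$labels[test_ids], scores[test_ids])
    }
  }
  metric_names <- c("auc", "aupr", "accuracy", "kappa", "mcc")
  rows <- lapply(raw, function(reps) {
    means <- vapply(metric_names, function(m)
      mean(vapply(reps, function(x) x[[m]], 0)), 0)
    as.list(means)
  })
  structure(list(rows = rows, raw = raw, n_repeats = as.integer(n_repeats),
                 base_seed = as.integer(base_seed)),
            class = "ablation_report")
}

#' @export
print.ablation_report <- function(x, ...) {
  cat(sprintf("ablation over %d repeats:\n", x$n_repeats))
  for (v in names(x$rows)) {
    r <- x$rows[[v]]
    cat(sprintf("  %-24s AUC %.3f AUPR %.3f acc %.3f kappa %.3f MCC %.3f\n",
                v, r$auc, r$aupr, r$accuracy, r$kappa, r$mcc))
  }
  invisible(x)
}

#' Write an ablation report (TSV summary + JSON with per-repeat detail)
#'
#' @param report An `ablation_report`.
#' @param path Output path stem; writes `<path>.tsv` and `<path>.json`.
#' @export
write_ablation_report <- function(report, path) {
  df <- do.call(rbind, lapply(names(report$rows), function(v)
    data.frame(variant = v, as.data.frame(report$rows[[v]]))))
  write.table(df, paste0(path, ".tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
  detail <- lapply(report$raw, function(reps) lapply(reps, unclass))
  jsonlite::write_json(list(means = report$rows, repeats = detail,
                            n_repeats = report$n_repeats),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
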