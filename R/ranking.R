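## Whole-library scoring, ranking and exclusion bookkeeping for
## repurposing candidate selection.

#' Score and rank a candidate library
#'
#' Scores every molecule with a trained model (ensemble or baseline) and
#' orders them by descending score, ties broken lexicographically by id.
#' Ranks follow the competition convention: `rank = 1 + number of
#' strictly greater scores`, so tied drugs share a rank.  Unscorable
#' molecules are collected in the `rejects` attribute rather than
#' silently dropped.
#'
#' @param model An `mpnn_ensemble`, `mpnn_model` or `baseline_model`.
#' @param library Molecule table to rank.
#' @param features Optional `feature_table` for auxiliary blocks.
#' @return A `ranked_list` data.frame: `rank`, `id`, `score`,
#'   `excluded`, `exclusion_reason`.
#' @export
rank_library <- function(model, library, features = NULL) {
  if (!nrow(library)) .stopf("library is empty")
  scores <- if (inherits(model, "baseline_model")) predict(model, library)
            else predict(model, library, features = features)
  rejects <- names(scores)[is.na(scores)]
  ok <- scores[!is.na(scores)]
  ord <- order(-ok, names(ok))
  ok <- ok[ord]
  rk <- vapply(ok, function(s) 1L + sum(ok > s), 0L)
  out <- data.frame(rank = unname(rk), id = names(ok), score = unname(ok),
                    excluded = FALSE, exclusion_reason = NA_character_,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "rejects") <- rejects
  class(out) <- c("ranked_list", "data.frame")
  out
}

#' Flag known actives in a ranked list
#'
#' Drugs with documented anti-cancer activity keep their ranks but are
#' flagged excluded, mirroring candidate selection where such drugs are
#' set aside rather than removed from the ordering.
#'
#' @param ranked A `ranked_list`.
#' @param known_actives Character vector of drug ids.
#' @param reason Exclusion annotation.
#' @return The annotated `ranked_list`.
#' @export
apply_exclusions <- function(ranked, known_actives,
                             reason = "documented anti-cancer activity") {
  missing <- setdiff(known_actives, ranked$id)
  if (length(missing))
    .warnf("%d exclusion ids absent from the ranked list (e.g. %s)",
           length(missing), missing[1])
  hit <- ranked$id %in% known_actives
  ranked$excluded <- ranked$excluded | hit
  ranked$exclusion_reason[hit] <- reason
  ranked
}

#' Write a ranked list as TSV
#'
#' `rank<TAB>id<TAB>score<TAB>excluded<TAB>reason`.
#' @param ranked A `ranked_list`.
#' @param path TSV path.
#' @export
write_ranked_list <- function(ranked, path) {
  write.table(as.data.frame(ranked), path, sep = "\t", row.names = FALSE, quote = FALSE)
}
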