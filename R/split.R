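## Balanced scaffold-based splitting.  Molecules are grouped by
## Bemis-Murcko scaffold; whole groups are assigned to partitions so no
## scaffold spans train and test, which measures generalization to new
## chemotypes rather than memorization of frameworks.

#' Scaffold-based train/validation/test split
#'
#' Groups molecules by scaffold, forces groups larger than half the
#' target test size into train, and greedily assigns the remaining
#' (seed-shuffled) groups to fill validation and test toward the size
#' fractions.  With `balanced = TRUE` several seeded shuffles are tried
#' and the assignment whose validation/test class ratios sit closest to
#' the overall positive rate is kept.
#'
#' @param dataset A `labeled_dataset`.
#' @param fractions Train/validation/test fractions, positive, summing
#'   to 1 (default `c(0.8, 0.1, 0.1)`).
#' @param seed RNG seed.
#' @param balanced Balance class ratios across partitions (default
#'   `TRUE`).
#' @param n_attempts Shuffles tried when balancing (default 20).
#' @return A `split_plan`: `assignment` (named factor train/validation/
#'   test), `fractions`, `seed`, `scaffold_of`.
#' @export
scaffold_split <- function(dataset, fractions = c(0.8, 0.1, 0.1), seed = 1L,
                           balanced = TRUE, n_attempts = 20L) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  if (length(fractions) != 3 || any(fractions <= 0) || abs(sum(fractions) - 1) > 1e-8)
    .stopf("fractions must be three positive numbers summing to 1")
  ids <- dataset$molecules$id
  scaff <- bemis_murcko_scaffold(dataset$molecules$canonical_smiles)
  names(scaff) <- ids
  groups <- split(ids, scaff)
  if (length(groups) < 2) .stopf("dataset needs at least 2 scaffold groups")
  n <- length(ids)
  t_val <- fractions[2] * n
  t_test <- fractions[3] * n
  sizes <- lengths(groups)
  big <- sizes > t_test / 2
  if (all(big)) {
    .stopf("infeasible split: every scaffold group exceeds half the test size (e.g. scaffold '%s')",
           names(groups)[which.max(sizes)])
  }
  small_idx <- which(!big)
  overall <- mean(dataset$labels[ids] == 1)
  pos_in <- vapply(groups, function(g) sum(dataset$labels[g] == 1), 0)
  tol <- max(1, ceiling(0.015 * n))
  attempt <- function(sub_seed) {
    set.seed(sub_seed)
    ordr <- small_idx[sample.int(length(small_idx))]
    part <- rep("train", length(groups))
    s_val <- s_test <- 0
    for (gi in ordr) {
      g <- sizes[gi]
      d_val <- t_val - s_val; d_test <- t_test - s_test
      # accept a group only if it moves the partition closer to target
      fit_val <- d_val > 0 && g <= 2 * d_val
      fit_test <- d_test > 0 && g <= 2 * d_test
      if (fit_test && (d_test >= d_val || !fit_val)) {
        part[gi] <- "test"; s_test <- s_test + g
      } else if (fit_val) {
        part[gi] <- "validation"; s_val <- s_val + g
      }
    }
    # repair pass: top off any residual deficit from train-assigned groups
    for (p in c("validation", "test")) {
      target <- if (p == "validation") t_val else t_test
      repeat {
        d <- target - sum(sizes[part == p])
        if (d <= tol) break
        cand <- which(part == "train" & !big & sizes <= 2 * d)
        if (!length(cand)) break
        gi <- cand[which.max(sizes[cand])]
        part[gi] <- p
      }
    }
    part
  }
  score_part <- function(part) {
    dev <- function(p) {
      k <- part == p
      if (!any(k)) return(Inf)
      abs(sum(pos_in[k]) / sum(sizes[k]) - overall)
    }
    max(dev("validation"), dev("test"))
  }
  sub_seeds <- .derive_seeds(seed, max(1L, if (balanced) n_attempts else 1L))
  best <- NULL; best_score <- Inf
  for (ss in sub_seeds) {
    part <- attempt(ss)
    sc <- score_part(part)
    if (sc < best_score) { best <- part; best_score <- sc }
    if (!balanced || sc <= 0.02) break
  }
  part <- best
  if (!any(part == "test") || !any(part == "validation"))
    .stopf("infeasible split: could not fill validation/test (largest scaffold '%s')",
           names(groups)[which.max(sizes)])
  assignment <- character(n); names(assignment) <- ids
  for (k in seq_along(groups)) assignment[groups[[k]]] <- part[k]
  structure(list(assignment = assignment[ids], fractions = fractions,
                 seed = as.integer(seed), scaffold_of = scaff),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  tab <- table(factor(x$assignment, c("train", "validation", "test")))
  cat(sprintf("split_plan (seed %d): train %d / validation %d / test %d over %d scaffolds\n",
              x$seed, tab[1], tab[2], tab[3], length(unique(x$scaffold_of))))
  invisible(x)
}

#' Write a split plan as TSV (`id<TAB>partition<TAB>scaffold`)
#'
#' @param plan A `split_plan`.
#' @param path TSV path.
#' @export
write_split_plan <- function(plan, path) {
  write.table(data.frame(id = names(plan$assignment),
                         partition = unname(plan$assignment),
                         scaffold = unname(plan$scaffold_of[names(plan$assignment)])),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Ids of one partition of a split plan
#' @param plan A `split_plan`.
#' @param partition `"train"`, `"validation"` or `"test"`.
#' @export
split_ids <- function(plan, partition = c("train", "validation", "test")) {
  partition <- match.arg(partition)
  names(plan$assignment)[plan$assignment == partition]
}
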