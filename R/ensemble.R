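# Majority-vote ensembling and feature-importance table constructions.

#' Majority vote over classifier predictions
#'
#' Per image, the most frequent label among the voters wins; ties are broken
#' by the fixed group order (A-MTrP < L-MTrP < healthy) and counted in the
#' `"n_ties"` attribute of the result.
#'
#' @param votes Matrix or data frame (rows = images, columns = voters) of
#'   group labels; at least one voter and one image.
#' @return Factor of winning labels with attribute `n_ties`.
#' @export
majority_vote <- function(votes) {
  votes <- as.matrix(votes)
  if (nrow(votes) == 0L || ncol(votes) == 0L) stop("empty vote set")
  if (!all(votes %in% GROUP_LEVELS)) stop("votes must be valid group labels")
  n_ties <- 0L
  winners <- apply(votes, 1, function(v) {
    cnt <- vapply(GROUP_LEVELS, function(g) sum(v == g), 0L)
    if (sum(cnt == max(cnt)) > 1L) n_ties <<- n_ties + 1L
    GROUP_LEVELS[which.max(cnt)]
  })
  structure(factor(winners, levels = GROUP_LEVELS), n_ties = n_ties)
}

#' Majority-vote ensemble of the selected classifiers for one approach
#'
#' Runs [evaluate_loso()] for each selected (technique, param) on the
#' approach's feature table, majority-votes the per-image predictions, and
#' returns the ensembled confusion counts and metrics.
#'
#' @param table A [feature_table()].
#' @param selected Data frame from [grid_select()] (`technique`, `param`).
#' @param seed Master seed.
#' @param hidden NN hidden width.
#' @return `list(votes, predictions, confusion, metrics, n_ties)`.
#' @export
ensemble_vote <- function(table, selected, seed = 1L, hidden = 512L) {
  if (nrow(selected) < 3L) stop("majority vote needs at least 3 voters")
  votes <- sapply(seq_len(nrow(selected)), function(i) {
    r <- evaluate_loso(table, selected$technique[i], selected$param[i],
                       seed = derive_seed(seed, 100L + i), hidden = hidden)
    as.character(r$predictions$pred)
  })
  colnames(votes) <- paste(selected$technique, selected$param, sep = ":")
  win <- majority_vote(votes)
  predictions <- data.frame(site_id = table$site_id, group = table$group,
                            pred = win)
  cm <- confusion_counts(predictions)
  list(votes = votes, predictions = predictions, confusion = cm,
       metrics = classification_metrics(cm), n_ties = attr(win, "n_ties"))
}

# Mean-aggregates one statistic across an approach's feature columns:
# identity for the 7-feature approaches, the mean of the 40 (Gabor) or 8
# (SEGL direction) instances otherwise.
#' @keywords internal
aggregate_stat <- function(table, feature) {
  cols <- grep(paste0("_", feature, "$"), colnames(table), value = TRUE)
  if (!length(cols)) stop("no columns for feature ", feature)
  rowMeans(as.matrix(table[, cols, drop = FALSE]))
}

#' @keywords internal
check_aligned <- function(tables) {
  ref <- tables[[1]]
  for (t in tables[-1])
    if (!identical(t$site_id, ref$site_id) ||
        !identical(as.character(t$group), as.character(ref$group)))
      stop("feature tables are not row-aligned")
  invisible(TRUE)
}

#' Single-statistic reduced feature table
#'
#' Keeps one statistical feature across the four approaches: the named
#' statistic is taken directly from the B-mode and LBP tables and
#' mean-aggregated over its 40 (Gabor) or 8 (SEGL) instances, giving a
#' 4-value vector per image.
#'
#' @param tables Named list of the four [feature_table()]s
#'   (`bmode`, `lbp`, `gabor`, `segl`), row-aligned.
#' @param feature One of the seven statistic names.
#' @return A `feature_table` with 4 feature columns `<approach>_<feature>`.
#' @export
single_feature_table <- function(tables, feature) {
  feature <- match.arg(feature, STAT_NAMES)
  check_aligned(tables)
  out <- data.frame(site_id = tables[[1]]$site_id,
                    group = tables[[1]]$group)
  for (ap in names(tables))
    out[[paste0(ap, "_", feature)]] <- aggregate_stat(tables[[ap]], feature)
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Leave-one-statistic-out reduced feature table
#'
#' Removes one statistical feature and keeps the remaining six, each
#' mean-aggregated per approach as in [single_feature_table()]: 6 x 4 = 24
#' values per image.
#'
#' @param tables Named list of the four [feature_table()]s.
#' @param removed_feature Statistic to remove.
#' @return A `feature_table` with 24 feature columns.
#' @export
ablation_table <- function(tables, removed_feature) {
  removed_feature <- match.arg(removed_feature, STAT_NAMES)
  check_aligned(tables)
  out <- data.frame(site_id = tables[[1]]$site_id,
                    group = tables[[1]]$group)
  for (feature in setdiff(STAT_NAMES, removed_feature))
    for (ap in names(tables))
      out[[paste0(ap, "_", feature)]] <- aggregate_stat(tables[[ap]], feature)
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Feature-importance ranking
#'
#' Combines the single-statistic and leave-one-out metrics into one ranked
#' report and identifies the best single statistic (highest accuracy) and
#' the most damaging removal (lowest accuracy).
#'
#' @param single_metrics Data frame: `feature` plus metric columns, one row
#'   per single-statistic run.
#' @param ablation_metrics Data frame: `feature` (the removed statistic)
#'   plus metric columns, one row per removal run.
#' @return Data frame with `mode` (`"single"`/`"ablation"`), sorted by
#'   accuracy within mode; attributes `best_single` and `worst_ablation`.
#' @export
importance_report <- function(single_metrics, ablation_metrics) {
  s <- single_metrics[order(-single_metrics$accuracy), , drop = FALSE]
  a <- ablation_metrics[order(-ablation_metrics$accuracy), , drop = FALSE]
  s$mode <- "single"; a$mode <- "ablation"
  out <- rbind(s, a)
  rownames(out) <- NULL
  attr(out, "best_single") <- s$feature[1]
  attr(out, "worst_ablation") <- a$feature[nrow(a)]
  out
}
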