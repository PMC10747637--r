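# One-way ANOVA comparisons of each (approach, statistic) across the three
# groups.

#' Aggregate one feature into per-group observation vectors
#'
#' Multi-instance features (Gabor, SEGL) are mean-aggregated per image; with
#' `unit = "site"` the images of a site are further averaged into one
#' observation per site.
#'
#' @param table A [feature_table()].
#' @param feature Statistic name.
#' @param unit `"image"` (default) or `"site"`.
#' @return Named list of three numeric vectors (one per group).
#' @export
aggregate_observations <- function(table, feature, unit = c("image", "site")) {
  unit <- match.arg(unit)
  val <- aggregate_stat(table, feature)
  grp <- factor(table$group, levels = GROUP_LEVELS)
  if (unit == "site") {
    agg <- stats::aggregate(val, by = list(site = table$site_id,
                                           group = grp), FUN = mean)
    val <- agg$x
    grp <- factor(agg$group, levels = GROUP_LEVELS)
  }
  split(val, grp)
}

#' One-way ANOVA of three groups
#'
#' Classic between/within sum-of-squares decomposition,
#' `F = MS_between / MS_within`, p from the F distribution with
#' `(k - 1, n - k)` degrees of freedom.  Degenerate conventions: if both the
#' between- and within-group variances are zero, `F = 0`, `p = 1`; if only
#' the within-group variance is zero, `F = Inf`, `p = 0`.  F is invariant to
#' shifting all observations by a constant and to positive rescaling.
#'
#' @param groups List of numeric vectors, each of length >= 2.
#' @return List of class `anova_result`: `F`, `p`, `df`, `group_means`,
#'   `group_sds`, `n`.
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups))
  if (any(vapply(groups, length, 0L) < 2L))
    stop("every group needs at least 2 observations")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
  k <- length(groups); n <- length(y)
  ssb <- sum(vapply(groups, function(v) length(v) * (mean(v) - mean(y))^2, 0))
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 0))
  if (ssw <= 1e-12 * max(ssb, 1e-300)) {
    if (ssb <= 0) { F <- 0; p <- 1 } else { F <- Inf; p <- 0 }
  } else {
    a <- stats::anova(stats::lm(y ~ g))
    F <- a$`F value`[1]
    p <- a$`Pr(>F)`[1]
  }
  structure(list(F = F, p = p, df = c(k - 1L, n - k),
                 group_means = vapply(groups, mean, 0),
                 group_sds = vapply(groups, stats::sd, 0),
                 n = vapply(groups, length, 0L)),
            class = "anova_result")
}

#' Group-comparison summary over all approaches and statistics
#'
#' Runs [one_way_anova()] for each of the 7 statistics x 4 approaches (28
#' rows), reporting per-group means and standard deviations, the raw p
#' value, a significance flag at `alpha`, and (for information only) the
#' Bonferroni-adjusted p value.
#'
#' @param tables Named list of the four [feature_table()]s.
#' @param unit `"image"` or `"site"` observations.
#' @param alpha Significance level for the flag column (default 0.05).
#' @return Data frame with 28 rows.
#' @export
anova_table <- function(tables, unit = c("image", "site"), alpha = 0.05) {
  unit <- match.arg(unit)
  approaches <- intersect(c("gabor", "segl", "bmode", "lbp"), names(tables))
  rows <- list()
  for (feature in STAT_NAMES) {
    for (ap in approaches) {
      obs <- aggregate_observations(tables[[ap]], feature, unit)
      a <- one_way_anova(obs)
      rows[[length(rows) + 1L]] <- data.frame(
        feature = feature, approach = ap,
        F = a$F, p_value = a$p,
        mean_A = a$group_means[["A-MTrP"]], sd_A = a$group_sds[["A-MTrP"]],
        mean_healthy = a$group_means[["healthy"]],
        sd_healthy = a$group_sds[["healthy"]],
        mean_L = a$group_means[["L-MTrP"]], sd_L = a$group_sds[["L-MTrP"]],
        significant = a$p < alpha)
    }
  }
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p_value * nrow(out))
  rownames(out) <- NULL
  out
}
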