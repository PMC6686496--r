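#' Scoring power: correlation and regression error against experiment
#'
#' Pearson correlation between predicted score and experimental affinity
#' (pK units), and the root mean squared residual of the ordinary
#' least-squares fit `affinity ~ score` (intercept included) — the two
#' headline numbers of a scoring-power benchmark.
#'
#' @param records Data frame with columns `score` (higher = better
#'   predicted binding) and `affinity`.
#' @return One-row tibble: `n`, `pcc`, `rmse`.
#' @examples
#' d <- data.frame(score = 1:5, affinity = c(2, 4, 5, 4, 8))
#' scoring_power(d)
#' @export
scoring_power <- function(records) {
  stopifnot(all(c("score", "affinity") %in% names(records)))
  records <- as_tibble(records)
  if (nrow(records) < 3L) {
    stop_dfire("scoring power needs at least 3 records", "dfire_domain")
  }
  if (stats::sd(records$score) == 0 || stats::sd(records$affinity) == 0) {
    stop_dfire("zero variance in score or affinity", "dfire_domain")
  }
  fit <- lm(affinity ~ score, data = records)
  tibble(n = nrow(records),
         pcc = cor(records$score, records$affinity),
         rmse = sqrt(mean(fit$residuals^2)))
}

# rank ligands best-first with the documented stable tie policy:
# descending score, ties by input order
.rank_screen <- function(set) {
  stopifnot(all(c("score", "is_active") %in% names(set)))
  set <- as_tibble(set)
  n_active <- sum(set$is_active)
  if (n_active == 0L || n_active == nrow(set)) {
    stop_dfire("screening set needs at least one active and one decoy",
               "dfire_domain")
  }
  set[order(-set$score, seq_len(nrow(set))), ]
}

#' Enrichment factor at top x%
#'
#' How many times more actives sit in the top `x_percent` of the
#' score-ranked library than random selection would put there:
#' `EF = (N_true / N_selected) / (N_active / N_total)` with
#' `N_selected = ceiling(x% * N_total)`. Score ties are broken by input
#' order (stable), so the metric is deterministic.
#'
#' @param set Data frame with `score` and logical `is_active`.
#' @param x_percent Selection fraction in percent, in (0, 100].
#' @return One-row tibble: `x_percent`, `n_selected`, `n_true`, `ef`.
#' @examples
#' set <- data.frame(score = 100:1, is_active = rep(c(TRUE, FALSE), 50))
#' enrichment_factor(set, 10)
#' @export
enrichment_factor <- function(set, x_percent = 1) {
  stopifnot(x_percent > 0, x_percent <= 100)
  ranked <- .rank_screen(set)
  n_total <- nrow(ranked)
  n_active <- sum(ranked$is_active)
  n_sel <- ceiling(x_percent / 100 * n_total)
  n_true <- sum(ranked$is_active[seq_len(n_sel)])
  tibble(x_percent = x_percent, n_selected = n_sel, n_true = n_true,
         ef = (n_true / n_sel) / (n_active / n_total))
}

#' ROC curve of a screening set
#'
#' Vertices of the trapezoidal ROC (ties merged into single diagonal
#' segments), starting at (0, 0).
#'
#' @param set Data frame with `score` and logical `is_active`.
#' @return Tibble with columns `fpr`, `tpr`.
#' @export
roc_curve <- function(set) {
  ranked <- .rank_screen(set)
  n_a <- sum(ranked$is_active)
  n_d <- nrow(ranked) - n_a
  # merge tied scores: one vertex after each distinct score value
  grp <- cumsum(!duplicated(ranked$score))
  tp <- cumsum(ranked$is_active)
  fp <- cumsum(!ranked$is_active)
  last <- !duplicated(grp, fromLast = TRUE)
  tibble(fpr = c(0, fp[last] / n_d), tpr = c(0, tp[last] / n_a))
}

#' ROC AUC of a screening set
#'
#' Rank-based area under the ROC curve: the probability that a random
#' active outscores a random decoy, ties counting one half
#' (equivalently the normalized Wilcoxon statistic).
#'
#' @inheritParams roc_curve
#' @return AUC as a fraction in `[0, 1]`.
#' @export
roc_auc <- function(set) {
  ranked <- .rank_screen(set)
  n_a <- sum(ranked$is_active)
  n_d <- nrow(ranked) - n_a
  r <- rank(ranked$score)        # average ranks handle ties as 1/2
  (sum(r[ranked$is_active]) - n_a * (n_a + 1) / 2) / (n_a * n_d)
}

#' Early-enrichment logAUC of a screening set
#'
#' Area under the ROC curve drawn against `log10(FPR)` on
#' `FPR in [lambda, 1]`, normalized by `log10(1/lambda)` and expressed
#' in percent. The log axis weights the low-false-positive region where
#' virtual screens operate. The piecewise-linear (trapezoidal) ROC is
#' integrated exactly on the log axis: over a segment where
#' `TPR = a + b*FPR`, the contribution is
#' `(a*log(f2/f1) + b*(f2 - f1)) / log(10)`. Random scores give
#' `100 * (1 - lambda) / log(1/lambda)` (about 14.5% at the default
#' `lambda`), not 50%.
#'
#' @inheritParams roc_curve
#' @param lambda Lower FPR bound of the log axis (default 0.001).
#' @return logAUC in percent.
#' @export
log_auc <- function(set, lambda = 0.001) {
  stopifnot(lambda > 0, lambda < 1)
  rc <- roc_curve(set)
  f <- rc$fpr
  t <- rc$tpr
  # interpolate the curve at fpr = lambda, then keep fpr >= lambda
  if (max(f) < lambda) {
    stop_dfire("ROC does not reach fpr = lambda", "dfire_domain")
  }
  # TPR at fpr = lambda along the curve; on a vertical stack at lambda
  # take its top, matching the segment integration below
  i1 <- max(which(f <= lambda))
  t_l <- if (f[i1] == lambda || i1 == length(f)) t[i1] else
    t[i1] + (t[i1 + 1L] - t[i1]) * (lambda - f[i1]) / (f[i1 + 1L] - f[i1])
  keep <- f > lambda
  f <- c(lambda, f[keep])
  t <- c(t_l, t[keep])
  # exact integral of the piecewise-linear ROC in log10(fpr)
  area <- 0
  for (s in seq_len(length(f) - 1L)) {
    f1 <- f[s]; f2 <- f[s + 1L]
    if (f2 <= f1) next      # vertical segment: no log-x extent
    b <- (t[s + 1L] - t[s]) / (f2 - f1)
    a <- t[s] - b * f1
    area <- area + (a * log(f2 / f1) + b * (f2 - f1)) / log(10)
  }
  100 * area / log10(1 / lambda)
}

#' Docking power: native-pose recovery success rates
#'
#' A complex counts as a success at `top_n` if any of its `top_n`
#' best-scored poses lies within 2.0 Angstrom RMSD of the native pose
#' (strict `<`). Poses are ranked by descending `score` (input order on
#' ties).
#'
#' @param pose_table Data frame with `complex_id`, `score`, `rmsd`.
#' @param top_n Integer vector of depths to evaluate.
#' @param rmsd_cutoff Success threshold in Angstrom.
#' @return Tibble with `top_n`, `n_success`, `n_complexes`,
#'   `success_rate` (percent).
#' @export
docking_power <- function(pose_table, top_n = 1:3, rmsd_cutoff = 2.0) {
  stopifnot(all(c("complex_id", "score", "rmsd") %in% names(pose_table)))
  if (anyNA(pose_table$rmsd)) {
    stop_dfire("missing RMSD values", "dfire_domain")
  }
  pt <- as_tibble(pose_table) |>
    mutate(.ord = row_number()) |>
    arrange(.data$complex_id, desc(.data$score), .data$.ord)
  per_complex <- pt |>
    group_by(.data$complex_id) |>
    summarise(rmsds = list(.data$rmsd), n_poses = n(), .groups = "drop")
  purrr::map_dfr(top_n, function(k) {
    short <- per_complex$n_poses < k
    if (any(short)) {
      stop_dfire(sprintf("complex %s has fewer than %d poses",
                         per_complex$complex_id[short][1], k),
                 "dfire_domain")
    }
    succ <- vapply(per_complex$rmsds,
                   function(r) any(r[seq_len(k)] < rmsd_cutoff), TRUE)
    tibble(top_n = k, n_success = sum(succ),
           n_complexes = nrow(per_complex),
           success_rate = 100 * mean(succ))
  })
}

#' Ranking power over ligand clusters
#'
#' For each cluster of ligands sharing a target: high-level success
#' means the predicted scores order every member exactly as the
#' experimental affinities do; low-level success means only that the
#' experimentally best binder gets the best predicted score. Clusters
#' with tied experimental affinities cannot be ranked unambiguously and
#' are skipped with a warning.
#'
#' @param records Data frame with `cluster_id`, `score`, `affinity`.
#' @return One-row tibble: `n_clusters`, `n_skipped`, `high_level`,
#'   `low_level` (success rates in percent).
#' @export
ranking_power <- function(records) {
  stopifnot(all(c("cluster_id", "score", "affinity") %in% names(records)))
  cl <- split(as_tibble(records), records$cluster_id)
  usable <- logical(length(cl))
  high <- low <- logical(length(cl))
  for (s in seq_along(cl)) {
    g <- cl[[s]]
    if (nrow(g) < 2L) {
      stop_dfire("every cluster needs at least 2 members", "dfire_domain")
    }
    if (anyDuplicated(g$affinity)) {
      warn(paste0("cluster '", names(cl)[s],
                  "' has tied experimental affinities; skipped"))
      next
    }
    usable[s] <- TRUE
    ord_pred <- order(-g$score, seq_len(nrow(g)))
    ord_exp <- order(-g$affinity)
    high[s] <- identical(ord_pred, ord_exp)
    low[s] <- ord_pred[1] == ord_exp[1]
  }
  if (!any(usable)) stop_dfire("no rankable clusters", "dfire_domain")
  tibble(n_clusters = sum(usable), n_skipped = sum(!usable),
         high_level = 100 * mean(high[usable]),
         low_level = 100 * mean(low[usable]))
}

#' Screening-power summary
#'
#' Convenience wrapper computing the usual screening metrics in one
#' call: enrichment factors at several depths, ROC AUC and logAUC.
#'
#' @param set Data frame with `score` and logical `is_active`.
#' @param ef_percents Depths for [enrichment_factor()].
#' @param lambda Lower bound for [log_auc()].
#' @return One-row tibble: `n_actives`, `n_decoys`, `auc`, `log_auc`,
#'   and one `ef_<x>` column per depth.
#' @export
screening_power <- function(set, ef_percents = c(1, 5, 10), lambda = 0.001) {
  efs <- purrr::map_dfr(ef_percents, function(x) enrichment_factor(set, x))
  out <- tibble(n_actives = sum(set$is_active),
                n_decoys = sum(!set$is_active),
                auc = roc_auc(set), log_auc = log_auc(set, lambda))
  for (s in seq_along(ef_percents)) {
    out[[paste0("ef_", ef_percents[s])]] <- efs$ef[s]
  }
  out
}
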