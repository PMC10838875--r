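#' Predict raw-scale sub-scores from volumes (generic)
#'
#' Interface used by the occlusion machinery: any model that can map a list of
#' volumes to an `n x n_tasks` matrix of predictions on the raw score scale
#' can be interrogated for region importance. Methods exist for
#' `cnn_ensemble` and for `volume_scorer` (a plain function wrapper, useful
#' for analytic oracles).
#'
#' @param model the predictor.
#' @param volumes list of `brain_volume`s.
#' @param ... method-specific arguments.
#' @return numeric matrix, one row per volume, one column per task.
#' @export
predict_scores <- function(model, volumes, ...) UseMethod("predict_scores")

#' @export
predict_scores.cnn_ensemble <- function(model, volumes, ...) {
  x <- if (is.matrix(volumes)) volumes else volumes_to_matrix(volumes)
  preds <- ensemble_forward(model, x, "prediction")
  p01 <- Reduce(`+`, preds) / length(preds)
  unscale_targets(p01, model$tasks, model$scales)
}

#' Wrap a plain function as a volume scorer
#'
#' @param fn function taking one `brain_volume`, returning a numeric vector of
#'   task predictions.
#' @param tasks task names.
#' @return An object of class `volume_scorer`.
#' @export
volume_scorer <- function(fn, tasks) {
  structure(list(fn = fn, tasks = tasks), class = "volume_scorer")
}

#' @export
predict_scores.volume_scorer <- function(model, volumes, ...) {
  out <- t(vapply(volumes, model$fn, numeric(length(model$tasks))))
  colnames(out) <- model$tasks
  out
}

#' Occlusion importance of one atlas region
#'
#' Relative change of the model's mean absolute error when region `i` is
#' occluded (filled with `fill`) in every input volume:
#' `|MAE_occluded - MAE| / MAE`. Scores are only comparable at a fixed fill
#' value.
#'
#' @param model a predictor with a [predict_scores()] method.
#' @param volumes list of `brain_volume`s.
#' @param y_true `n x n_tasks` matrix of true raw scores (columns named by
#'   task).
#' @param atlas an `atlas_parcellation`.
#' @param region_id region to occlude.
#' @param task task name.
#' @param fill occlusion fill intensity (0 = background in normalized units).
#' @return importance score (>= 0).
#' @export
region_importance <- function(model, volumes, y_true, atlas, region_id, task,
                              fill = 0) {
  tasks <- colnames(y_true)
  base <- predict_scores(model, volumes)
  mae0 <- mean(abs(y_true[, task] - base[, task]))
  if (mae0 == 0) stop("degenerate input: baseline MAE is zero")
  occ <- lapply(volumes, occlude_region, atlas = atlas,
                region_id = region_id, fill = fill)
  pocc <- predict_scores(model, occ)
  mae1 <- mean(abs(y_true[, task] - pocc[, task]))
  abs(mae1 - mae0) / mae0
}

occlusion_predictions <- function(model, volumes, atlas, fill = 0) {
  lapply(atlas$regions$region_id, function(r) {
    occ <- lapply(volumes, occlude_region, atlas = atlas, region_id = r,
                  fill = fill)
    predict_scores(model, occ)
  })
}

importance_from_predictions <- function(base, occ_list, y_true, regions,
                                        tasks, subset = NULL) {
  if (is.null(subset)) subset <- seq_len(nrow(base))
  rows <- list()
  for (tk in tasks) {
    mae0 <- mean(abs(y_true[subset, tk] - base[subset, tk]))
    if (mae0 == 0) stop("degenerate input: baseline MAE is zero for ", tk)
    for (ri in seq_along(regions)) {
      mae1 <- mean(abs(y_true[subset, tk] - occ_list[[ri]][subset, tk]))
      rows[[length(rows) + 1L]] <- data.frame(
        region_id = regions[ri], task = tk,
        score = abs(mae1 - mae0) / mae0, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Region x task occlusion-importance table
#'
#' Full sweep of [region_importance()] over every atlas region and task,
#' occluding each region once and reusing its predictions across tasks and
#' diagnosis sub-groups. When `subgroups` is given (a factor over volumes,
#' e.g. diagnosis), a per-subgroup table is emitted alongside the pooled one;
#' empty subgroups are skipped with a warning.
#'
#' @param model a predictor with a [predict_scores()] method.
#' @param volumes list of `brain_volume`s.
#' @param y_true `n x n_tasks` matrix of true raw scores, columns named by
#'   task.
#' @param atlas an `atlas_parcellation`.
#' @param tasks tasks to score (default: all columns of `y_true`).
#' @param subgroups optional factor of length `n` (e.g. CN/MCI/AD).
#' @param fill occlusion fill value.
#' @return data.frame with `region_id`, `region_name`, `task`, `subgroup`
#'   (`"all"` for the pooled table) and `score`; the fill value is attached as
#'   attribute `fill`.
#' @export
importance_table <- function(model, volumes, y_true, atlas,
                             tasks = colnames(y_true), subgroups = NULL,
                             fill = 0) {
  base <- predict_scores(model, volumes)
  occ <- occlusion_predictions(model, volumes, atlas, fill)
  regions <- atlas$regions$region_id
  out <- importance_from_predictions(base, occ, y_true, regions, tasks)
  out$subgroup <- "all"
  if (!is.null(subgroups)) {
    if (!is.factor(subgroups)) subgroups <- factor(subgroups)
    for (g in levels(subgroups)) {
      idx <- which(subgroups == g)
      if (!length(idx)) {
        warning("subgroup ", g, " is empty; skipped")
        next
      }
      tab <- importance_from_predictions(base, occ, y_true, regions, tasks,
                                         subset = idx)
      tab$subgroup <- g
      out <- rbind(out, tab)
    }
  }
  out <- merge(out, atlas$regions, by = "region_id", sort = FALSE)
  out <- out[order(out$subgroup, out$task, -out$score),
             c("region_id", "region_name", "task", "subgroup", "score")]
  rownames(out) <- NULL
  attr(out, "fill") <- fill
  out
}

#' Top-k regions per task
#'
#' @param imp an [importance_table()] result.
#' @param k how many regions per task.
#' @param subgroup which subgroup table to rank (default pooled).
#' @return data.frame of the k highest-scoring regions per task.
#' @export
top_regions <- function(imp, k = 5, subgroup = "all") {
  d <- imp[imp$subgroup == subgroup, ]
  do.call(rbind, lapply(split(d, d$task), function(g)
    head(g[order(-g$score), ], k)))
}

#' Permutation spread of occlusion importance
#'
#' Null distribution for importance scores: the subject-to-score assignment is
#' permuted (predictions are left untouched) and the full region x task
#' importance table is recomputed per permutation. Returns the per-permutation
#' maximum score; an observed score exceeding this spread indicates signal
#' beyond chance.
#'
#' @param model predictor.
#' @param volumes list of `brain_volume`s.
#' @param y_true raw-score matrix, columns named by task.
#' @param atlas an `atlas_parcellation`.
#' @param n_perm number of permutations.
#' @param fill occlusion fill value.
#' @param seed integer seed.
#' @return list with `max_per_perm` (length `n_perm`) and `spread`
#'   (their maximum).
#' @export
importance_permutation_spread <- function(model, volumes, y_true, atlas,
                                          n_perm = 99, fill = 0, seed = 1L) {
  base <- predict_scores(model, volumes)
  occ <- occlusion_predictions(model, volumes, atlas, fill)
  regions <- atlas$regions$region_id
  tasks <- colnames(y_true)
  with_seed(seed, {
    mx <- vapply(seq_len(n_perm), function(b) {
      yp <- y_true[sample.int(nrow(y_true)), , drop = FALSE]
      tab <- importance_from_predictions(base, occ, yp, regions, tasks)
      max(tab$score)
    }, numeric(1))
    list(max_per_perm = mx, spread = max(mx))
  })
}

#' Spearman correlation of sub-score importance profiles
#'
#' For each unordered pair of tasks, the Spearman rank correlation between
#' their region-importance vectors, with Benjamini-Hochberg adjustment of the
#' p-values across pairs. P-values follow the standard Spearman test: exact
#' (permutation) for small tie-free vectors, the asymptotic approximation
#' otherwise; ties receive average ranks.
#'
#' @param imp an [importance_table()] result (pooled subgroup is used).
#' @param alpha significance level for the flags.
#' @param exact force exact (`TRUE`) or asymptotic (`FALSE`) p-values;
#'   `NULL` (default) decides automatically.
#' @return list with matrices `rho`, `p`, `p_adj` and logical `significant`;
#'   class `subscore_correlation`.
#' @export
subscore_correlation <- function(imp, alpha = 0.05, exact = NULL) {
  d <- imp[imp$subgroup == "all", ]
  d <- d[order(d$task, d$region_id), ]  # align rows by region across tasks
  wide <- do.call(cbind, lapply(split(d$score, d$task), as.numeric))
  if (nrow(wide) < 3) stop("need at least 3 regions")
  tasks <- colnames(wide)
  k <- length(tasks)
  rho <- diag(1, k); dimnames(rho) <- list(tasks, tasks)
  p <- matrix(NA_real_, k, k, dimnames = list(tasks, tasks))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (sd(wide[, i]) == 0 || sd(wide[, j]) == 0)
      stop("undefined correlation: constant importance vector for ",
           tasks[if (sd(wide[, i]) == 0) i else j])
    ct <- suppressWarnings(
      cor.test(wide[, i], wide[, j], method = "spearman", exact = exact))
    rho[i, j] <- rho[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  up <- upper.tri(p)
  padj <- p
  padj[up] <- p.adjust(p[up], method = "BH")
  padj[lower.tri(padj)] <- t(padj)[lower.tri(padj)]
  structure(list(rho = rho, p = p, p_adj = padj,
                 significant = padj < alpha, alpha = alpha),
            class = "subscore_correlation")
}

#' @export
print.subscore_correlation <- function(x, ...) {
  cat("Spearman correlation of importance profiles:\n")
  print(round(x$rho, 3))
  cat("BH-adjusted p-values:\n")
  print(signif(x$p_adj, 3))
  invisible(x)
}
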