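#' Min-max scale sub-scores to [0, 1]
#'
#' Maps each sub-score column through `(x - min) / (max - min)` using its
#' declared scale, so the 13 items contribute on equal footing to the
#' classifier. Raw values outside the declared range are a validation error.
#'
#' @param scores data.frame containing sub-score columns `q1..q13` (extra
#'   columns are carried through unchanged).
#' @param scales per-score scale table, see [adas_scales()].
#' @return `scores` with the sub-score columns scaled to `[0, 1]`.
#' @export
minmax_scale <- function(scores, scales = adas_scales()) {
  for (j in seq_len(nrow(scales))) {
    s <- scales$score[j]
    if (!s %in% names(scores)) next
    if (scales$min[j] >= scales$max[j])
      stop("degenerate scale for ", s)
    x <- scores[[s]]
    if (any(x < scales$min[j] | x > scales$max[j], na.rm = TRUE))
      stop("raw ", s, " values outside declared range [",
           scales$min[j], ", ", scales$max[j], "]")
    scores[[s]] <- (x - scales$min[j]) / (scales$max[j] - scales$min[j])
  }
  scores
}

#' Binary diagnosis label: AD vs nAD
#'
#' Pools cognitively normal and MCI subjects into the non-AD (`nAD`) class.
#'
#' @param diagnosis factor/character vector with levels CN, MCI, AD.
#' @return factor with levels `nAD`, `AD`.
#' @export
ad_label <- function(diagnosis) {
  factor(ifelse(as.character(diagnosis) == "AD", "AD", "nAD"),
         levels = c("nAD", "AD"))
}

#' Class-balanced train/test split
#'
#' Splits subjects into train and test at the given ratio (stratified by
#' class, so each class is split at the same ratio), then balances each side
#' by randomly down-sampling its majority class. After balancing, class
#' counts within each side differ by at most one (zero under down-sampling).
#'
#' @param data data.frame with a `label` column (factor, two levels).
#' @param test_fraction held-out fraction (default 0.2).
#' @param seed integer seed; same seed gives identical membership.
#' @return list with `train` and `test` data.frames.
#' @export
balance_and_split <- function(data, test_fraction = 0.2, seed = 1L) {
  lab <- data$label
  if (nlevels(droplevels(factor(lab))) < 2L)
    stop("both classes must be present")
  with_seed(seed, {
    test_idx <- unlist(lapply(levels(factor(lab)), function(l) {
      i <- which(lab == l)
      sample(i, round(test_fraction * length(i)))
    }))
    balance <- function(d) {
      counts <- table(d$label)
      m <- min(counts)
      keep <- unlist(lapply(names(counts), function(l) {
        i <- which(d$label == l)
        if (length(i) > m) sample(i, m) else i
      }))
      d[sort(keep), , drop = FALSE]
    }
    list(train = balance(data[-test_idx, , drop = FALSE]),
         test = balance(data[test_idx, , drop = FALSE]))
  })
}

default_rf_grid <- function() {
  expand.grid(ntree = c(100L, 300L), nodesize = c(1L, 5L),
              maxnodes = c(NA_integer_, 256L))
}

#' Select the sub-scores most important for AD diagnosis
#'
#' Fits a random-forest AD-vs-nAD classifier on the scaled sub-scores with
#' grid-searched hyperparameters (selected by out-of-bag error on the training
#' set), and returns impurity-based feature importances normalized to sum to
#' one, the top-k sub-score identities, and test-set accuracy, precision and
#' recall (AD as the positive class).
#'
#' @param train,test data.frames with columns `q1..q13` (scaled) and `label`.
#' @param grid data.frame of hyperparameter combinations with columns
#'   `ntree`, `nodesize`, `maxnodes` (`NA` maxnodes = unbounded).
#' @param k how many top sub-scores to report (default 4).
#' @param seed integer seed.
#' @return list with `importance` (named, sorted, sums to 1), `top_k`,
#'   `metrics` (accuracy/precision/recall), `best_params`, `fit`.
#' @export
select_top_subscores <- function(train, test, grid = default_rf_grid(),
                                 k = 4, seed = 1L) {
  if (is.null(grid) || !nrow(grid)) stop("hyperparameter grid is empty")
  if (k > 13) stop("k must be <= 13")
  feats <- intersect(score_cols(), names(train))
  x_tr <- as.matrix(train[, feats]); y_tr <- train$label
  x_te <- as.matrix(test[, feats]); y_te <- test$label
  with_seed(seed, {
    # maxnodes cannot exceed the number of training cases
    mn <- function(i) {
      if (is.na(grid$maxnodes[i])) NULL
      else min(grid$maxnodes[i], nrow(x_tr))
    }
    oob <- vapply(seq_len(nrow(grid)), function(i) {
      fit <- randomForest::randomForest(
        x_tr, y_tr, ntree = grid$ntree[i], nodesize = grid$nodesize[i],
        maxnodes = mn(i))
      fit$err.rate[grid$ntree[i], "OOB"]
    }, numeric(1))
    best <- which.min(oob)
    fit <- randomForest::randomForest(
      x_tr, y_tr, ntree = grid$ntree[best], nodesize = grid$nodesize[best],
      maxnodes = mn(best), importance = FALSE)
    imp <- fit$importance[, "MeanDecreaseGini"]
    imp <- imp / sum(imp)
    imp <- sort(imp, decreasing = TRUE)
    pred <- predict(fit, x_te)
    tp <- sum(pred == "AD" & y_te == "AD")
    fp <- sum(pred == "AD" & y_te == "nAD")
    fn <- sum(pred == "nAD" & y_te == "AD")
    metrics <- c(accuracy = mean(pred == y_te),
                 precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                 recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
    list(importance = imp, top_k = names(imp)[seq_len(k)], metrics = metrics,
         best_params = grid[best, , drop = FALSE], fit = fit)
  })
}
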