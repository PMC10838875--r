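#' Area under the ROC curve
#'
#' AUROC of a continuous score for a binary label, computed with `pROC`
#' (positive class `AD`, higher scores indicating AD).
#'
#' @param labels factor with levels `nAD`, `AD`.
#' @param scores numeric scores (probability of AD or any monotone surrogate).
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(labels, scores) {
  as.numeric(pROC::auc(pROC::roc(labels, scores, levels = c("nAD", "AD"),
                                 direction = "<", quiet = TRUE)))
}

fit_lr <- function(x, y, lambda) {
  glmnet::glmnet(x, y, family = "binomial", alpha = 0, lambda = lambda)
}

#' Train diagnostic classifiers on penultimate-layer embeddings
#'
#' Fits a ridge-penalized logistic regression, a k-nearest-neighbour
#' classifier and a random forest on the training embeddings to predict AD vs
#' nAD, and evaluates each by AUROC on the held-out embeddings.
#'
#' @param emb_train,emb_test `n x width` embedding matrices.
#' @param y_train,y_test factors with levels `nAD`, `AD`.
#' @param k neighbours for KNN.
#' @param lambda ridge penalty for the logistic regression.
#' @param ntree random-forest size.
#' @param seed integer seed.
#' @return list with per-classifier `auroc`, AD-probability `scores`,
#'   predicted `labels` on the test embeddings, and fitted objects.
#' @export
train_diag_classifiers <- function(emb_train, y_train, emb_test, y_test,
                                   k = 5L, lambda = NULL, ntree = 200L,
                                   seed = 1L) {
  if (nlevels(droplevels(y_train)) < 2L)
    stop("both classes must be present in the training split")
  if (is.null(lambda)) lambda <- 1 / nrow(emb_train)  # unit-strength ridge
  with_seed(seed, {
    lr <- fit_lr(emb_train, y_train, lambda)
    lr_score <- as.numeric(predict(lr, emb_test, type = "response"))
    kn <- class::knn(emb_train, emb_test, y_train, k = k, prob = TRUE)
    win_prob <- attr(kn, "prob")
    knn_score <- ifelse(kn == "AD", win_prob, 1 - win_prob)
    rf <- randomForest::randomForest(emb_train, y_train, ntree = ntree)
    rf_score <- predict(rf, emb_test, type = "prob")[, "AD"]
    scores <- list(lr = lr_score, knn = knn_score, rf = rf_score)
    labels <- lapply(scores, function(s)
      factor(ifelse(s > 0.5, "AD", "nAD"), levels = c("nAD", "AD")))
    list(auroc = vapply(scores, function(s) auroc(y_test, s), numeric(1)),
         scores = scores, labels = labels,
         fits = list(lr = lr, knn_train = list(x = emb_train, y = y_train,
                                               k = k), rf = rf))
  })
}

#' Majority-vote diagnosis over ensemble members and classifiers
#'
#' Hard majority vote over all (ensemble member x classifier) predicted
#' labels. Ties are broken towards the positive (AD) class and flagged.
#'
#' @param label_sets list (over ensemble members) of lists (over classifiers)
#'   of predicted label factors, as produced by [train_diag_classifiers()]
#'   per member.
#' @return list with `labels` (factor `nAD`/`AD`), `ad_fraction` (vote share)
#'   and `tie` (logical).
#' @export
voting_predict <- function(label_sets) {
  votes <- do.call(cbind, lapply(label_sets, function(member)
    do.call(cbind, lapply(member, function(l) as.character(l) == "AD"))))
  if (is.null(dim(votes))) votes <- matrix(votes, ncol = 1)
  frac <- rowMeans(votes)
  tie <- frac == 0.5
  lab <- factor(ifelse(frac >= 0.5, "AD", "nAD"), levels = c("nAD", "AD"))
  if (any(tie))
    message(sum(tie), " tied vote(s) resolved towards AD")
  list(labels = lab, ad_fraction = frac, tie = tie)
}

#' Diagnostic extension of a trained ensemble
#'
#' Extracts FC2 embeddings from every ensemble member, trains the three
#' classifiers per member on the training split, evaluates AUROC per
#' member x classifier on the test split, and combines all member x classifier
#' label predictions by majority vote.
#'
#' @param ensemble a `cnn_ensemble`.
#' @param x_train,x_test `nvox x n` volume matrices.
#' @param y_train,y_test AD/nAD label factors.
#' @param seed integer seed.
#' @param ... passed to [train_diag_classifiers()].
#' @return list with `auroc` (member x classifier matrix), `vote`
#'   (from [voting_predict()]), `vote_auroc` (AUROC of the vote share), and
#'   `accuracy` of the voted labels.
#' @export
diagnose_extension <- function(ensemble, x_train, y_train, x_test, y_test,
                               seed = 1L, ...) {
  emb_tr <- extract_embeddings(ensemble, x_train)
  emb_te <- extract_embeddings(ensemble, x_test)
  per_member <- lapply(seq_along(emb_tr), function(m)
    train_diag_classifiers(emb_tr[[m]], y_train, emb_te[[m]], y_test,
                           seed = seed + m, ...))
  aur <- do.call(rbind, lapply(per_member, `[[`, "auroc"))
  vote <- voting_predict(lapply(per_member, `[[`, "labels"))
  list(auroc = aur, vote = vote,
       vote_auroc = auroc(y_test, vote$ad_fraction),
       accuracy = mean(vote$labels == y_test))
}
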