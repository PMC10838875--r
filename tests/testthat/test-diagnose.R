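test_that("AUROC agrees with the brute-force all-pairs oracle", {
  brute_auc <- function(labels, scores) {
    pos <- scores[labels == "AD"]; neg <- scores[labels == "nAD"]
    mean(outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q)))
  }
  set.seed(41)
  for (i in 1:5) {
    n <- 150
    lab <- factor(sample(c("nAD", "AD"), n, TRUE), levels = c("nAD", "AD"))
    sc <- rnorm(n) + 0.8 * (lab == "AD")
    expect_equal(auroc(lab, sc), brute_auc(lab, sc), tolerance = 1e-12)
  }
  # ROC symmetry: AUROC of s and of -s sum to 1
  lab <- factor(rep(c("nAD", "AD"), 50), levels = c("nAD", "AD"))
  sc <- rnorm(100)
  expect_equal(auroc(lab, sc) + auroc(lab, -sc), 1, tolerance = 1e-12)
})

test_that("diagnostic classifiers separate separable embeddings", {
  set.seed(42)
  n <- 120
  y <- factor(rep(c("nAD", "AD"), each = n / 2), levels = c("nAD", "AD"))
  x <- matrix(rnorm(n * 8), n, 8)
  x[y == "AD", 1] <- x[y == "AD", 1] + 10  # linearly separable
  idx <- sample(n, 80)
  fit <- train_diag_classifiers(x[idx, ], y[idx], x[-idx, ], y[-idx],
                                seed = 1)
  expect_equal(unname(fit$auroc[["lr"]]), 1.0)
  expect_gt(fit$auroc[["knn"]], 0.95)
  expect_gt(fit$auroc[["rf"]], 0.95)
  expect_error(train_diag_classifiers(x[y == "AD", ], y[y == "AD"],
                                      x, y), "both classes")
})

test_that("labels independent of embeddings give chance AUROC", {
  set.seed(43)
  n <- 1600
  y <- factor(sample(c("nAD", "AD"), n, TRUE), levels = c("nAD", "AD"))
  x <- matrix(rnorm(n * 5), n, 5)
  fit <- train_diag_classifiers(x[1:800, ], y[1:800], x[801:n, ], y[801:n],
                                seed = 2)
  expect_equal(unname(fit$auroc[["lr"]]), 0.5, tolerance = 0.07)
  expect_equal(unname(fit$auroc[["rf"]]), 0.5, tolerance = 0.07)
})

test_that("majority voting follows the vote share and flags ties", {
  lab <- function(x) factor(x, levels = c("nAD", "AD"))
  # unanimous
  v <- voting_predict(list(list(lab(c("AD", "nAD")))))
  expect_equal(as.character(v$labels), c("AD", "nAD"))
  # 2-of-3 positive
  v3 <- voting_predict(list(list(lab("AD"), lab("AD"), lab("nAD"))))
  expect_equal(as.character(v3$labels), "AD")
  expect_false(v3$tie)
  # even split resolves to AD with a flag
  expect_message(
    v2 <- voting_predict(list(list(lab("AD"), lab("nAD")))),
    "tied")
  expect_equal(as.character(v2$labels), "AD")
  expect_true(v2$tie)
})

test_that("embedding extraction matches the model's FC2 width", {
  cfg <- cnn_model_config(extent = 16L, channels = c(2L, 4L, 8L, 16L),
                          fc_widths = c(12L, 9L), n_tasks = 2L)
  m <- build_cnn(cfg, seed = 11)
  cp <- list(epoch = 1, test_mse = 0.1,
             params = cogscan:::cnn_get_params(m$ptr))
  ens <- suppressWarnings(select_ensemble(list(cp), cfg, adas_scales(),
                                          c("q1", "q4")))
  set.seed(3)
  x <- matrix(rnorm(16^3 * 4), 16^3, 4)
  emb <- extract_embeddings(ens, x)
  expect_length(emb, 1)
  expect_equal(dim(emb[[1]]), c(4L, 9L))
  # identical volumes give identical embedding rows
  e2 <- extract_embeddings(ens, cbind(x[, 1], x[, 1]))[[1]]
  expect_equal(e2[1, ], e2[2, ])
})
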