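test_that("min-max scaling maps declared ranges onto [0, 1] and validates", {
  sc <- adas_scales()
  d <- data.frame(q1 = c(0, 5, 10))
  expect_equal(minmax_scale(d, sc)$q1, c(0, 0.5, 1))
  expect_error(minmax_scale(data.frame(q1 = 11), sc), "outside declared")
  # an already-scaled column on a 0-1 scale is unchanged
  sc01 <- data.frame(score = "q1", min = 0, max = 1)
  expect_equal(minmax_scale(data.frame(q1 = c(0.2, 0.7)), sc01)$q1,
               c(0.2, 0.7))
  expect_error(minmax_scale(data.frame(q1 = 1),
                            data.frame(score = "q1", min = 2, max = 2)),
               "degenerate")
})

test_that("balanced splitting equalizes classes after an 80:20 split", {
  d <- data.frame(q1 = rnorm(1000),
                  label = factor(rep(c("nAD", "AD"), c(800, 200)),
                                 levels = c("nAD", "AD")))
  sp <- balance_and_split(d, test_fraction = 0.2, seed = 1)
  expect_equal(as.integer(table(sp$train$label)), c(160L, 160L))
  expect_equal(as.integer(table(sp$test$label)), c(40L, 40L))
  # post-balance class counts differ by at most one
  expect_lte(abs(diff(table(sp$test$label))), 1)
  # already balanced input loses nobody
  d2 <- data.frame(q1 = rnorm(100),
                   label = factor(rep(c("nAD", "AD"), 50)))
  sp2 <- balance_and_split(d2, seed = 2)
  expect_equal(nrow(sp2$train) + nrow(sp2$test), 100)
  # determinism
  sp3 <- balance_and_split(d, test_fraction = 0.2, seed = 1)
  expect_identical(sp$train, sp3$train)
  expect_error(balance_and_split(data.frame(label = factor(rep("AD", 5)))),
               "both classes")
})

test_that("AD labelling pools CN and MCI into nAD", {
  lab <- ad_label(c("CN", "MCI", "AD"))
  expect_equal(as.character(lab), c("nAD", "nAD", "AD"))
  expect_equal(levels(lab), c("nAD", "AD"))
})

test_that("random forest recovers the informative sub-scores", {
  # 4 of 13 sub-scores carry the diagnosis signal
  subs <- simulate_subscores(1000, seed = 21)
  scaled <- minmax_scale(subs)
  scaled$label <- ad_label(subs$diagnosis)
  sp <- balance_and_split(scaled, seed = 22)
  sel <- select_top_subscores(sp$train, sp$test, seed = 23)
  expect_setequal(sel$top_k, c("q1", "q4", "q7", "q8"))
  expect_equal(sum(sel$importance), 1, tolerance = 1e-12)
  expect_true(all(sel$importance >= 0))
  expect_gt(sel$metrics[["accuracy"]], 0.6)
  expect_error(select_top_subscores(sp$train, sp$test, grid = NULL), "grid")
  expect_error(select_top_subscores(sp$train, sp$test, k = 14), "k must")
})

test_that("shuffled labels drive balanced-test accuracy to chance", {
  subs <- simulate_subscores(1000, seed = 31)
  scaled <- minmax_scale(subs)
  scaled$label <- cogscan:::with_seed(32, sample(ad_label(subs$diagnosis)))
  sp <- balance_and_split(scaled, seed = 33)
  sel <- select_top_subscores(sp$train, sp$test,
                              grid = data.frame(ntree = 100L, nodesize = 5L,
                                                maxnodes = NA_integer_),
                              seed = 34)
  expect_equal(unname(sel$metrics[["accuracy"]]), 0.5, tolerance = 0.08)
})
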