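ptab <- function(y_true, y_pred, task = "q1")
  data.frame(subject_id = seq_along(y_true), task = task,
             y_true = y_true, y_pred = y_pred)

test_that("MAE and R2 match hand-computed fixtures exactly", {
  expect_equal(mae(ptab(c(2, 4), c(3, 2)), "q1"), 1.5, tolerance = 1e-12)
  expect_equal(mae(ptab(c(1, 2, 3), c(1, 2, 3)), "q1"), 0)
  expect_equal(r_squared(ptab(c(1, 2, 3), c(1, 2, 4)), "q1"), 0.5,
               tolerance = 1e-12)
  expect_equal(r_squared(ptab(c(1, 2, 3), c(1, 2, 3)), "q1"), 1)
  # constant predictor at the mean scores zero
  expect_equal(r_squared(ptab(c(1, 2, 3), rep(2, 3)), "q1"), 0)
  expect_error(r_squared(ptab(c(2, 2), c(1, 2)), "q1"), "zero variance")
  expect_error(mae(ptab(1, 1), "q9"), "no predictions")
  # adding a perfect prediction never increases MAE
  base <- ptab(c(2, 4), c(3, 2))
  more <- rbind(base, data.frame(subject_id = 3, task = "q1", y_true = 5,
                                 y_pred = 5))
  expect_lte(mae(more, "q1"), mae(base, "q1"))
})

test_that("ITV matches Eq-style range on a hand fixture", {
  v <- data.frame(
    subject_id = c("a", "a", "a", "b"),
    visit_date = c("2024-01-01", "2024-02-01", "2024-03-01", "2024-01-01"),
    q1 = c(5, 7, 6, 3))
  itv <- compute_itv(v, "q1")
  expect_equal(itv$per_entry$itv[1:3], c(2, 2, 2))
  # single visit in window: ITV 0, excluded from the mean by default
  expect_equal(itv$per_entry$itv[4], 0)
  expect_equal(itv$mean_itv, 2)
  inc <- compute_itv(v, "q1", include_singletons = TRUE)
  expect_equal(inc$mean_itv, 1.5)
  # all identical scores
  v$q1 <- 4
  expect_equal(compute_itv(v, "q1")$mean_itv, 0)
  v$visit_date[1] <- "not-a-date"
  expect_error(compute_itv(v, "q1"), "date")
})

test_that("ITV agrees with an O(n^2) brute-force oracle on random tables", {
  brute_itv <- function(visits, score, window) {
    d <- as.numeric(as.Date(visits$visit_date))
    q <- visits[[score]]
    out <- numeric(nrow(visits))
    for (i in seq_len(nrow(visits))) {
      vals <- c()
      for (j in seq_len(nrow(visits))) {
        if (visits$subject_id[j] == visits$subject_id[i] &&
            abs(d[j] - d[i]) <= window)
          vals <- c(vals, q[j])
      }
      out[i] <- max(vals) - min(vals)
    }
    out
  }
  for (seed in 1:5) {
    subs <- simulate_subscores(40, seed = seed)
    v <- simulate_visits(subs, visits_per_subject = 5, fluctuation_sd = 2,
                         seed = seed + 100)
    got <- compute_itv(v, "q4", window_days = 91)
    expect_equal(got$per_entry$itv, brute_itv(v, "q4", 91))
  }
})

test_that("ITV is invariant to row order and date translation", {
  subs <- simulate_subscores(30, seed = 3)
  v <- simulate_visits(subs, visits_per_subject = 4, fluctuation_sd = 1,
                       seed = 5)
  base <- compute_itv(v, "q1")$mean_itv
  perm <- v[sample(nrow(v)), ]
  expect_equal(compute_itv(perm, "q1")$mean_itv, base)
  shifted <- v
  shifted$visit_date <- format(as.Date(v$visit_date) + 500, "%Y-%m-%d")
  expect_equal(compute_itv(shifted, "q1")$mean_itv, base)
})

test_that("the MAE-vs-ITV test matches the reference t-test", {
  set.seed(7)
  err <- abs(rnorm(50, 2, 1)); itv <- abs(rnorm(60, 1.5, 1))
  got <- compare_mae_itv(err, itv)
  ref <- t.test(err, itv, alternative = "greater")
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  # identical samples: t = 0, one-sided p = 0.5, flagged n.s.
  x <- c(1, 2, 3)
  same <- compare_mae_itv(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 0.5)
  expect_true(same$ns)
  # a +5 sigma shift is overwhelmingly significant
  big <- compare_mae_itv(itv + 5, itv)
  expect_lt(big$p, 0.001)
  # swapping samples flips the one-sided p (equal-variance symmetric case)
  a <- c(1, 2, 3, 4); b <- c(2, 3, 4, 5)
  expect_equal(compare_mae_itv(a, b)$p + compare_mae_itv(b, a)$p, 1,
               tolerance = 1e-12)
  expect_error(compare_mae_itv(rep(1, 3), rep(1, 3)), "degenerate")
})
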