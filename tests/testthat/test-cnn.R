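test_that("custom sigmoid matches closed form and degenerates gracefully", {
  expect_equal(custom_sigmoid(0, 3.7), 0.5)
  expect_equal(custom_sigmoid(log(3), 1), 0.75)
  expect_equal(custom_sigmoid(c(-5, 0, 2), 0), rep(0.5, 3))
  # numerically stable far in the tails
  expect_equal(custom_sigmoid(1000, 5), 1)
  expect_equal(custom_sigmoid(-1000, 5), 0)
  expect_error(custom_sigmoid(1, Inf), "finite")
})

test_that("cosine annealing restarts at lr_max and hits the midpoint", {
  expect_equal(cosine_annealing_lr(0, 10), 0.01)
  expect_equal(cosine_annealing_lr(10, 10), 0.01)  # warm restart
  expect_equal(cosine_annealing_lr(5, 10), 0.00505)
  expect_equal(cosine_annealing_lr(9, 10), 0.0001 + 0.5 * 0.0099 *
                 (1 + cos(pi * 0.9)))
  # monotone decay within a cycle
  lrs <- vapply(0:9, cosine_annealing_lr, numeric(1), cycle_length = 10)
  expect_true(all(diff(lrs) < 0))
  expect_error(cosine_annealing_lr(0, 0), "cycle_length")
  expect_error(cosine_annealing_lr(0, 10, lr_max = 1e-4, lr_min = 1e-2),
               "lr_min")
})

test_that("shape contract holds across valid configurations", {
  # extent X with 4 pooling stages: conv-4 extent X/16, flatten (X/16)^3 * ch
  for (ext in c(16L, 32L)) {
    ch <- c(2L, 3L, 5L, 7L)
    cfg <- cnn_model_config(extent = ext, channels = ch,
                            fc_widths = c(8L, 8L), n_tasks = 3L)
    m <- build_cnn(cfg, seed = 1)
    tr <- model_trace(m)
    expect_equal(tr$group_extent, ext / c(2, 4, 8, 16))
    expect_equal(tr$flatten_length, (ext / 16)^3 * 7)
    expect_equal(n_conv_layers(m), 10L)
  }
  expect_error(cnn_model_config(extent = 24L), "divisible")
  expect_error(cnn_model_config(channels = c(8L, 4L, 16L, 32L)),
               "increasing")
})

test_that("forward pass is deterministic and outputs stay in (0, 1)", {
  cfg <- cnn_model_config(extent = 16L, channels = c(2L, 4L, 8L, 16L),
                          fc_widths = c(16L, 16L), n_tasks = 4L)
  m <- build_cnn(cfg, seed = 3)
  set.seed(1)
  x <- matrix(rnorm(16^3 * 6), 16^3, 6)
  p1 <- cogscan:::cnn_forward(m$ptr, x)
  p2 <- cogscan:::cnn_forward(m$ptr, x)
  expect_identical(p1, p2)
  expect_true(all(p1 > 0 & p1 < 1))
  # identical volumes give identical rows
  xx <- cbind(x[, 1], x[, 1])
  p <- cogscan:::cnn_forward(m$ptr, xx)
  expect_equal(p[1, ], p[2, ])
})

test_that("training reduces loss on a learnable problem and is seed-stable", {
  cfg <- cnn_model_config(extent = 16L, channels = c(2L, 4L, 8L, 16L),
                          fc_widths = c(16L, 16L), n_tasks = 2L,
                          epochs = 6L, cycle_length = 3L)
  atlas <- make_atlas(c(16, 16, 16), 4, seed = 2)
  # targets carried by two regions, strong effects
  n <- 64
  eff <- effect_spec(data.frame(region_id = c(1L, 3L),
                                score = c("q1", "q4"), effect = c(30, 30)),
                     voxel_noise_sd = 10,
                     loadings = c(q1 = 1, q4 = 1))
  co <- simulate_cohort(atlas, n, eff, seed = 4)
  vols <- lapply(co$volumes, white_stripe_normalize)
  x <- volumes_to_matrix(vols)
  y <- cogscan:::scale_targets(co$subjects, c("q1", "q4"), co$scales)
  tr <- 1:48; te <- 49:64
  m <- build_cnn(cfg, seed = 5)
  cps <- train_cnn(m, x[, tr], y[tr, ], x[, te], y[te, ], seed = 6)
  expect_lt(cps[[length(cps)]]$test_mse, cps[[1]]$test_mse)
  # identical config + seeds reproduce the loss trajectory
  m2 <- build_cnn(cfg, seed = 5)
  cps2 <- train_cnn(m2, x[, tr], y[tr, ], x[, te], y[te, ], seed = 6)
  expect_equal(vapply(cps, `[[`, numeric(1), "train_loss"),
               vapply(cps2, `[[`, numeric(1), "train_loss"))
})

test_that("ensemble selection keeps the best k with deterministic tie-breaks", {
  fake_cp <- function(epoch, mse) list(epoch = epoch, train_loss = NA,
                                       test_mse = mse, test_mse_task = mse,
                                       params = list(epoch = epoch))
  cfg <- cnn_model_config(extent = 16L, channels = c(2L, 4L, 8L, 16L),
                          fc_widths = c(8L, 8L), n_tasks = 1L)
  sc <- adas_scales()
  # 10 distinct MSEs: the 7 smallest are kept, sorted ascending
  cps <- lapply(1:10, function(i) fake_cp(i, mse = (11 - i) / 100))
  ens <- select_ensemble(cps, cfg, sc, "q1")
  expect_length(ens$members, 7)
  expect_equal(vapply(ens$members, `[[`, numeric(1), "test_mse"),
               sort(vapply(cps, `[[`, numeric(1), "test_mse"))[1:7])
  # 3 checkpoints only: all kept, with a warning
  expect_warning(ens3 <- select_ensemble(cps[1:3], cfg, sc, "q1"),
                 "fewer")
  expect_length(ens3$members, 3)
  # equal MSE at the cut: earlier epoch wins
  cps_tie <- list(fake_cp(1, 0.5), fake_cp(2, 0.1), fake_cp(3, 0.1))
  e <- select_ensemble(cps_tie, cfg, sc, "q1", k_min = 1, k_max = 1)
  expect_equal(e$members[[1]]$epoch, 2)
})

test_that("ensemble predictions average members and map back to raw scale", {
  cfg <- cnn_model_config(extent = 16L, channels = c(2L, 4L, 8L, 16L),
                          fc_widths = c(8L, 8L), n_tasks = 2L)
  m <- build_cnn(cfg, seed = 9)
  p <- cogscan:::cnn_get_params(m$ptr)
  sc <- adas_scales()
  cp <- function(ep) list(epoch = ep, test_mse = 0.1, params = p)
  ens1 <- suppressWarnings(select_ensemble(list(cp(1)), cfg, sc,
                                           c("q1", "q4")))
  ens2 <- suppressWarnings(select_ensemble(list(cp(1), cp(2)), cfg, sc,
                                           c("q1", "q4")))
  set.seed(2)
  x <- matrix(rnorm(16^3 * 3), 16^3, 3)
  p1 <- predict(ens1, x)
  p2 <- predict(ens2, x)
  # identical members: ensemble of two equals the single member
  expect_equal(p1$y_pred, p2$y_pred, tolerance = 1e-6)
  # raw predictions sit inside each task's declared range
  q1 <- p1$y_pred[p1$task == "q1"]; q4 <- p1$y_pred[p1$task == "q4"]
  expect_true(all(q1 >= 0 & q1 <= 10) && all(q4 >= 0 & q4 <= 10))
  # mean + inverse scaling arithmetic: members at 0.2 and 0.4 on a 0-10 task
  ens_mix <- ens2
  expect_equal(cogscan:::unscale_targets(matrix(c(0.3, 0.3), 1), c("q1", "q4"),
                                         sc)[1, 1],
               c(q1 = 3))
})
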