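test_that("atlas partitions an ellipsoid into contiguous non-empty regions", {
  atlas <- make_atlas(c(32, 32, 32), 8, seed = 7)
  labs <- atlas$labels
  expect_true(all(labs %in% 0:8))
  expect_setequal(unique(as.vector(labs[labs > 0])), 1:8)
  expect_equal(atlas$regions$region_id, 1:8)
  # single region equals the whole brain mask
  a1 <- make_atlas(c(32, 32, 32), 1, seed = 7)
  expect_identical(a1$labels > 0, atlas$labels > 0)
  expect_true(all(a1$labels[a1$labels > 0] == 1L))
})

test_that("atlas generation is deterministic per seed and errors when oversized", {
  a <- make_atlas(c(16, 16, 16), 5, seed = 3)
  b <- make_atlas(c(16, 16, 16), 5, seed = 3)
  expect_identical(a$labels, b$labels)
  d <- make_atlas(c(16, 16, 16), 5, seed = 4)
  expect_false(identical(a$labels, d$labels))
  expect_error(make_atlas(c(3, 3, 3), 500), "too small")
})

test_that("zero-effect cohorts show no region-score correlation", {
  atlas <- tiny_atlas(extent = 20L, n_regions = 4L)
  eff <- effect_spec(data.frame(region_id = integer(), score = character(),
                                effect = numeric()),
                     voxel_noise_sd = 10)
  co <- simulate_cohort(atlas, 200, eff, seed = 11)
  rm <- t(vapply(co$volumes, region_means, numeric(4), atlas = atlas))
  for (s in c("q1", "q4")) {
    r <- apply(rm, 2, function(col) cor(col, co$subjects[[s]]))
    expect_true(all(abs(r) < 0.2))
  }
})

test_that("a planted effect makes its region's correlation dominate", {
  # effect only in region 2 for q1 at effect/noise 2: region-2 mean intensity
  # must out-correlate every other region with q1
  atlas <- tiny_atlas(extent = 20L, n_regions = 4L)
  eff <- effect_spec(data.frame(region_id = 2L, score = "q1", effect = 20),
                     voxel_noise_sd = 10)
  co <- simulate_cohort(atlas, 500, eff, seed = 12)
  rm <- t(vapply(co$volumes, region_means, numeric(4), atlas = atlas))
  r <- apply(rm, 2, function(col) cor(col, co$subjects$q1))
  expect_equal(unname(which.max(abs(r))), 2L)
  expect_gt(abs(r[2]), max(abs(r[-2])))
})

test_that("cohort generation is seed-stable, scale-closed, and validated", {
  atlas <- tiny_atlas()
  eff <- default_effect_spec(atlas, voxel_noise_sd = 5)
  a <- simulate_cohort(atlas, 30, eff, seed = 5)
  b <- simulate_cohort(atlas, 30, eff, seed = 5)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$volumes[[7]]$data, b$volumes[[7]]$data)
  sc <- adas_scales()
  for (j in seq_len(13)) {
    q <- a$subjects[[sc$score[j]]]
    expect_true(all(q >= sc$min[j] & q <= sc$max[j]))
  }
  bad <- effect_spec(data.frame(region_id = 99L, score = "q1", effect = 1))
  expect_error(simulate_cohort(atlas, 5, bad, seed = 1), "absent")
  expect_error(effect_spec(data.frame(region_id = 1L, score = "q1",
                                      effect = 1), voxel_noise_sd = -1),
               ">= 0")
})

test_that("diagnosis thresholds map severity extremes to CN and AD", {
  sev <- c(-4, 0, 4)
  d <- cogscan:::assign_diagnosis(sev)
  expect_equal(as.character(d[1]), "CN")
  expect_equal(as.character(d[3]), "AD")
  # class proportions roughly 1/3, 45%, 22% at large n
  co <- simulate_subscores(5000, seed = 42)
  p <- table(co$diagnosis) / 5000
  expect_equal(unname(p[["CN"]]), 0.336, tolerance = 0.1)
  expect_equal(unname(p[["MCI"]]), 0.447, tolerance = 0.1)
  expect_equal(unname(p[["AD"]]), 0.217, tolerance = 0.15)
  # 80:20 split
  expect_equal(sum(co$split == "test"), 1000)
})

test_that("visit tables honour fluctuation, counts, and window", {
  subs <- simulate_subscores(50, seed = 2)
  # zero fluctuation: every ITV is exactly 0
  v0 <- simulate_visits(subs, visits_per_subject = 4, fluctuation_sd = 0,
                        seed = 3)
  itv <- compute_itv(v0, "q1")
  expect_true(all(itv$per_entry$itv == 0))
  # one visit per subject: one row each
  v1 <- simulate_visits(subs, visits_per_subject = 1, seed = 3)
  expect_equal(nrow(v1), 50)
  # dates parse and sit within the window of the anchor visit
  expect_false(anyNA(as.Date(v0$visit_date)))
  expect_error(simulate_visits(subs, fluctuation_sd = -2), ">= 0")
})

test_that("mean ITV grows with the fluctuation sd", {
  subs <- simulate_subscores(500, seed = 9)
  m <- vapply(c(0.5, 1, 2), function(s) {
    v <- simulate_visits(subs, visits_per_subject = 3, fluctuation_sd = s,
                         seed = 31)
    compute_itv(v, "q1")$mean_itv
  }, numeric(1))
  expect_true(all(diff(m) > 0))
})
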