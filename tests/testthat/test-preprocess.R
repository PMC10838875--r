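test_that("brain mask zeroes non-brain voxels and validates geometry", {
  atlas <- tiny_atlas()
  arr <- array(1, dim = dim(atlas$labels))
  vol <- brain_volume(arr, "MRI")
  masked <- apply_brain_mask(vol, atlas)
  expect_true(all(masked$data[atlas$labels == 0] == 0))
  expect_true(all(masked$data[atlas$labels > 0] == 1))
  # an all-brain atlas leaves the volume unchanged
  full <- atlas
  full$labels[] <- 1L
  expect_identical(apply_brain_mask(vol, full)$data, vol$data)
  small <- make_atlas(c(8, 8, 8), 2)
  expect_error(apply_brain_mask(vol, small), "shapes differ")
})

test_that("NAWM estimation finds the high-intensity mode of a mixture", {
  vol <- mixture_volume(grey = 60, white = 100, sd = 8, wf = 0.4)
  est <- estimate_nawm(vol)
  expect_equal(est$mode, 100, tolerance = 2)
  expect_gt(est$sd, 0)
  # oracle: dense-histogram argmax over the upper half of the intensities
  v <- vol$data[vol$data != 0]
  h <- hist(v[v > median(v)], breaks = 200, plot = FALSE)
  expect_equal(est$mode, h$mids[which.max(h$counts)], tolerance = 3)
  # flat image is degenerate
  flat <- brain_volume(array(5, dim = c(8, 8, 8)), "MRI")
  expect_error(estimate_nawm(flat), "degenerate")
  # widening the half-width widens the stripe
  n1 <- estimate_nawm(vol, half_width = 0.02)
  n2 <- estimate_nawm(vol, half_width = 0.10)
  expect_gt(sum(n2$mask), sum(n1$mask))
})

test_that("white-stripe maps the NAWM mode to the reference", {
  vol <- mixture_volume(grey = 200, white = 300, sd = 30, wf = 0.4, seed = 4)
  ref <- ws_reference(mu_ref = 100, sigma_ref = 10)
  norm <- white_stripe_normalize(vol, ref)
  est <- estimate_nawm(norm)
  expect_equal(est$mode, 100, tolerance = 2)
  # oracle: the same affine map applied voxelwise
  nawm <- attr(norm, "nawm")
  brain <- vol$data != 0
  expect_equal(norm$data[brain],
               (vol$data[brain] - nawm$mode) / nawm$sd * 10 + 100,
               tolerance = 1e-12)
  # identity: a volume already at the reference is (nearly) unchanged
  renorm <- white_stripe_normalize(norm, ref)
  expect_lt(max(abs(renorm$data - norm$data)), 1.5)
})

test_that("white-stripe is affine-equivariant and idempotent", {
  vol <- mixture_volume(seed = 6)
  ref <- ws_reference(mu_ref = 0, sigma_ref = 1)
  n1 <- white_stripe_normalize(vol, ref)
  shifted <- vol
  shifted$data[shifted$data != 0] <- 3 * shifted$data[shifted$data != 0] + 40
  n2 <- white_stripe_normalize(shifted, ref)
  expect_equal(n1$data, n2$data, tolerance = 0.05)
  # idempotence: renormalizing moves the mode by less than the QC tolerance
  n3 <- white_stripe_normalize(n1, ref)
  expect_lt(abs(estimate_nawm(n3)$mode - 0), 0.5 * ref$sigma_ref)
})

test_that("white-stripe QC flags shifted volumes and keeps good ones", {
  vol <- mixture_volume(seed = 8)
  ref <- ws_reference(mu_ref = 0, sigma_ref = 1)
  norm <- white_stripe_normalize(vol, ref)
  qc <- qc_white_stripe(norm, ref, tolerance = 5)
  expect_true(qc$pass)
  shifted <- norm
  shifted$data[shifted$data != 0] <- shifted$data[shifted$data != 0] + 15
  qc2 <- qc_white_stripe(shifted, ref, tolerance = 5)
  expect_false(qc2$pass)
  expect_equal(qc2$deviation, 15, tolerance = 1)
  # inclusive boundary: a deviation exactly at the tolerance passes
  qc3 <- qc_white_stripe(shifted, ref, tolerance = qc2$deviation)
  expect_true(qc3$pass)
})

test_that("PET cohort normalization matches the percentile + max oracle", {
  mk <- function(vals) {
    arr <- array(0, dim = c(4, 4, 4))
    arr[seq_along(vals)] <- vals
    brain_volume(arr, "FDG-PET")
  }
  # three training images whose 99.9th percentiles are ~{2.0, 4.0, 3.1}
  tr <- list(mk(rep(2, 60)), mk(rep(4, 60)), mk(rep(3.1, 60)))
  out <- cohort_normalize_pet(tr)
  expect_equal(out$stats$n_stats, c(2, 4, 3.1))
  expect_equal(out$stats$divisor, 4)
  expect_equal(max(out$volumes[[1]]$data), 0.5)
  # constant training image: all scaled voxels equal 1
  one <- cohort_normalize_pet(list(mk(rep(7, 50))))
  expect_true(all(one$volumes[[1]]$data[one$volumes[[1]]$data != 0] == 1))
  # values above the divisor are retained unclipped (and reported)
  expect_message(
    big <- cohort_normalize_pet(tr, list(mk(rep(4.8, 60)))),
    "above 1")
  expect_equal(max(big$volumes[[1]]$data), 1.2)
  expect_error(cohort_normalize_pet(list()), "empty")
})

test_that("the 99.9th percentile matches a sort-based oracle", {
  # linear interpolation between order statistics on small random grids
  set.seed(33)
  for (i in 1:5) {
    v <- runif(16^3, 0, 10)
    arr <- array(v, dim = c(16, 16, 16))
    vol <- brain_volume(arr, "FDG-PET")
    got <- suppressMessages(cohort_normalize_pet(list(vol))$stats$n_stats)
    s <- sort(v[v != 0])
    h <- (length(s) - 1) * 0.999
    oracle <- s[floor(h) + 1] * (1 - (h - floor(h))) +
      s[floor(h) + 2] * (h - floor(h))
    expect_equal(got, oracle, tolerance = 1e-12)
  }
  # divisor is invariant to training-image order
  set.seed(34)
  vols <- lapply(1:4, function(i)
    brain_volume(array(runif(512, 0, i), dim = c(8, 8, 8)), "FDG-PET"))
  d1 <- cohort_normalize_pet(vols)$stats$divisor
  d2 <- cohort_normalize_pet(rev(vols))$stats$divisor
  expect_identical(d1, d2)
})
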