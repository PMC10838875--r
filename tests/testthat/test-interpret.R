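test_that("region occlusion touches exactly the region's voxels", {
  atlas <- tiny_atlas()
  set.seed(1)
  vol <- brain_volume(array(rnorm(16^3, 10), dim = c(16, 16, 16)), "MRI")
  occ <- occlude_region(vol, atlas, 2, fill = -1)
  expect_true(all(occ$data[atlas$labels == 2] == -1))
  expect_identical(occ$data[atlas$labels != 2], vol$data[atlas$labels != 2])
  expect_error(occlude_region(vol, atlas, 99), "unknown region")
  # occluding every region in turn touches each brain voxel exactly once
  touched <- array(0L, dim = dim(vol$data))
  for (r in atlas$regions$region_id) {
    o <- occlude_region(vol, atlas, r, fill = Inf)
    touched <- touched + (is.infinite(o$data))
  }
  expect_true(all(touched[atlas$labels > 0] == 1L))
  expect_true(all(touched[atlas$labels == 0] == 0L))
})

test_that("occlusion importance matches a brute-force oracle on a linear scorer", {
  # scorer reads only region 2 for q1 and region 3 for q4
  atlas <- tiny_atlas(extent = 12L, n_regions = 4L, seed = 2)
  scorer <- region_mean_scorer(atlas, c(q1 = 2, q4 = 3))
  set.seed(8)
  vols <- lapply(1:20, function(i)
    brain_volume(array(rnorm(12^3, 5, 2), dim = c(12, 12, 12)), "MRI",
                 subject_id = paste0("s", i)))
  y <- predict_scores(scorer, vols) + matrix(rnorm(40, 0, 0.1), 20, 2)
  colnames(y) <- c("q1", "q4")
  # independent re-evaluation loop
  brute <- function(region, task) {
    p0 <- t(vapply(vols, scorer$fn, numeric(2)))
    mae0 <- mean(abs(y[, task] - p0[, match(task, c("q1", "q4"))]))
    p1 <- t(vapply(vols, function(v) {
      v$data[atlas$labels == region] <- 0
      scorer$fn(v)
    }, numeric(2)))
    mae1 <- mean(abs(y[, task] - p1[, match(task, c("q1", "q4"))]))
    abs(mae1 - mae0) / mae0
  }
  for (r in 1:4) for (tk in c("q1", "q4")) {
    expect_equal(region_importance(scorer, vols, y, atlas, r, tk),
                 brute(r, tk), tolerance = 1e-10)
  }
  # a model provably independent of a region scores exactly 0
  expect_equal(region_importance(scorer, vols, y, atlas, 1, "q1"), 0)
  expect_equal(region_importance(scorer, vols, y, atlas, 4, "q4"), 0)
})

test_that("importance tables sweep regions, rank, and honour subgroups", {
  atlas <- tiny_atlas(extent = 12L, n_regions = 4L, seed = 2)
  scorer <- region_mean_scorer(atlas, c(q1 = 2, q4 = 3))
  set.seed(9)
  vols <- lapply(1:30, function(i)
    brain_volume(array(rnorm(12^3, 5, 2), dim = c(12, 12, 12)), "MRI"))
  y <- predict_scores(scorer, vols) + matrix(rnorm(60, 0, 0.05), 30, 2)
  colnames(y) <- c("q1", "q4")
  groups <- factor(rep(c("CN", "MCI", "AD"), each = 10),
                   levels = c("CN", "MCI", "AD"))
  imp <- importance_table(scorer, vols, y, atlas, subgroups = groups)
  expect_setequal(unique(imp$subgroup), c("all", "CN", "MCI", "AD"))
  expect_equal(sum(imp$subgroup == "all"), 4 * 2)
  expect_true(all(imp$score >= 0))
  # the scored region dominates its own task
  expect_equal(top_regions(imp, k = 1)["q1", "region_id"], 2)
  expect_equal(top_regions(imp, k = 1)["q4", "region_id"], 3)
  # empty subgroup warns and is skipped
  g2 <- factor(rep(c("CN", "MCI"), 15), levels = c("CN", "MCI", "AD"))
  expect_warning(imp2 <- importance_table(scorer, vols, y, atlas,
                                          subgroups = g2), "empty")
  expect_false("AD" %in% imp2$subgroup)
})

test_that("Spearman correlations and BH adjustment match hand computation", {
  # 6-region toy table with hand-assigned scores
  imp <- data.frame(
    region_id = rep(1:6, 3),
    region_name = rep(sprintf("r%d", 1:6), 3),
    task = rep(c("q1", "q4", "q7"), each = 6),
    subgroup = "all",
    score = c(1, 2, 3, 4, 5, 6,      # q1
              2, 1, 4, 3, 6, 5,      # q4: mild shuffle
              6, 5, 4, 3, 2, 1))     # q7: exact reversal of q1
  out <- subscore_correlation(imp, exact = FALSE)
  # oracle: Pearson on ranks
  rk <- function(x) cor(rank(x), rank(x))
  expect_equal(out$rho["q1", "q7"], -1)
  expect_equal(out$rho["q1", "q4"],
               cor(rank(c(1:6)), rank(c(2, 1, 4, 3, 6, 5))),
               tolerance = 1e-12)
  expect_equal(out$rho["q4", "q7"], -out$rho["q1", "q4"], tolerance = 1e-12)
  # identical columns correlate at exactly 1
  imp2 <- imp
  imp2$score[imp2$task == "q4"] <- imp2$score[imp2$task == "q1"]
  out2 <- subscore_correlation(imp2, exact = FALSE)
  expect_equal(out2$rho["q1", "q4"], 1)
  # BH adjustment equals the reference implementation on the three pairs
  praw <- out$p[upper.tri(out$p)]
  expect_equal(out$p_adj[upper.tri(out$p_adj)], p.adjust(praw, "BH"))
  # symmetry and unit diagonal
  expect_identical(out$rho, t(out$rho))
  expect_true(all(diag(out$rho) == 1))
  # constant importance vector is an error
  imp3 <- imp
  imp3$score[imp3$task == "q1"] <- 2
  expect_error(subscore_correlation(imp3), "constant")
})

test_that("spearman p-values agree with the reference on random input", {
  set.seed(11)
  for (i in 1:5) {
    x <- rnorm(20); z <- rnorm(20)
    imp <- data.frame(region_id = rep(1:20, 2),
                      region_name = "r", task = rep(c("q1", "q4"), each = 20),
                      subgroup = "all", score = abs(c(x, z)))
    out <- subscore_correlation(imp)
    ref <- cor.test(abs(x), abs(z), method = "spearman")
    expect_equal(out$rho["q1", "q4"], unname(ref$estimate), tolerance = 1e-12)
    expect_equal(out$p["q1", "q4"], ref$p.value, tolerance = 1e-12)
  }
})
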