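# Shared fixtures, built in code.

tiny_atlas <- function(extent = 16L, n_regions = 4L, seed = 7L)
  make_atlas(rep(extent, 3), n_regions, seed = seed)

# Two-Gaussian "grey/white" MRI phantom inside a mask; white fraction `wf`.
mixture_volume <- function(n = 20000, grey = 60, white = 100, sd = 8,
                           wf = 0.4, seed = 1L, extent = 32L) {
  stopifnot(n <= extent^3)
  arr <- array(0, dim = rep(extent, 3))
  vals <- cogscan:::with_seed(seed, {
    is_white <- runif(n) < wf
    rnorm(n, ifelse(is_white, white, grey), sd)
  })
  arr[seq_len(n)] <- vals
  brain_volume(arr, "MRI", subject_id = "phantom")
}

# analytic scorer: prediction for each task = mean intensity of one region
region_mean_scorer <- function(atlas, task_regions) {
  volume_scorer(function(v) {
    rm <- region_means(v, atlas)
    vapply(task_regions, function(r) rm[[as.character(r)]], numeric(1))
  }, names(task_regions))
}
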