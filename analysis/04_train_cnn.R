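#!/usr/bin/env Rscript
# Stage 4 — train the multi-task 3D CNN and ensemble the best checkpoints.
#
# Targets are the four selected sub-scores, min-max scaled; the loss is the
# mean per-task MSE; Adam under a single cosine-annealing cycle
# (desk peak rate 0.001); one checkpoint per epoch; the 5-7 checkpoints with
# the lowest test MSE form the prediction ensemble.

library(cogscan)

volumes <- readRDS("scratch/run/volumes_norm.rds")
subjects <- readRDS("scratch/run/subjects_kept.rds")
cohort <- readRDS("scratch/run/cohort.rds")
tasks <- c("q1", "q4", "q7", "q8")
seed <- 4L

tr <- subjects$split == "train"
x_tr <- volumes_to_matrix(volumes[tr])
x_te <- volumes_to_matrix(volumes[!tr])
scale01 <- function(d) sapply(tasks, function(s) {
  sc <- cohort$scales[cohort$scales$score == s, ]
  (d[[s]] - sc$min) / (sc$max - sc$min)
})
y_tr <- scale01(subjects[tr, ]); y_te <- scale01(subjects[!tr, ])

cfg <- cnn_model_config(n_tasks = length(tasks))
model <- build_cnn(cfg, seed = seed)
cps <- train_cnn(model, x_tr, y_tr, x_te, y_te, seed = seed + 1L,
                 verbose = TRUE)
ens <- select_ensemble(cps, cfg, cohort$scales, tasks)

hist <- data.frame(epoch = sapply(cps, `[[`, "epoch"),
                   train_loss = sapply(cps, `[[`, "train_loss"),
                   test_mse = sapply(cps, `[[`, "test_mse"))
write.csv(hist, "results/training_history.csv", row.names = FALSE)
saveRDS(ens, "scratch/run/ensemble.rds")

cat("Ensemble members (epoch @ test MSE):",
    paste(sprintf("%d@%.4f", sapply(ens$members, `[[`, "epoch"),
                  sapply(ens$members, `[[`, "test_mse")), collapse = ", "),
    "\n")
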