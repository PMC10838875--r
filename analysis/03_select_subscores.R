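#!/usr/bin/env Rscript
# Stage 3 — which sub-scores matter for AD diagnosis?
#
# A random-forest AD-vs-nAD classifier on the 13 min-max-scaled sub-scores
# (classes balanced by down-sampling within an 80:20 split, hyperparameters
# grid-searched by OOB error) ranks the items by impurity importance. The
# top four become the regression targets of the imaging model.

library(cogscan)

subjects <- readRDS("scratch/run/subjects_kept.rds")
seed <- 3L

scaled <- minmax_scale(subjects)
scaled$label <- ad_label(subjects$diagnosis)
sp <- balance_and_split(scaled, test_fraction = 0.2, seed = seed)
sel <- select_top_subscores(sp$train, sp$test, k = 4, seed = seed)

jsonlite::write_json(
  list(importance = as.list(sel$importance), top_k = sel$top_k,
       metrics = as.list(sel$metrics),
       best_params = as.list(sel$best_params)),
  "results/subscore_selection.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE)

cat("Selected sub-scores:", paste(sel$top_k, collapse = ", "), "\n")
cat("Their importance share:",
    round(sum(sel$importance[sel$top_k]) * 100), "%\n")
cat("Test accuracy/precision/recall:",
    paste(round(sel$metrics, 3), collapse = " / "), "\n")
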