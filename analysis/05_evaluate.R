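#!/usr/bin/env Rscript
# Stage 5 — prediction accuracy against the inter-test-variability benchmark.
#
# MAE and R-squared per sub-score on the held-out volumes; the mean ITV
# (max - min of each participant's scores within +/- 91 days) is the clinical
# yardstick: a one-tailed Welch test asks whether the model's errors exceed
# the natural visit-to-visit fluctuation.

library(cogscan)

volumes <- readRDS("scratch/run/volumes_norm.rds")
subjects <- readRDS("scratch/run/subjects_kept.rds")
visits <- readRDS("scratch/run/visits.rds")
ens <- readRDS("scratch/run/ensemble.rds")
tasks <- c("q1", "q4", "q7", "q8")

te <- subjects$split == "test"
y_raw <- as.matrix(subjects[te, tasks])
pred <- predict(ens, volumes[te], subject_ids = subjects$subject_id[te],
                y_true = y_raw)
metrics <- evaluate_predictions(pred, visits, window_days = 91)

write.csv(pred, "results/predictions.csv", row.names = FALSE)
write.csv(metrics, "results/metrics.csv", row.names = FALSE)
jsonlite::write_json(metrics, "results/metrics.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
saveRDS(pred, "scratch/run/predictions.rds")

print(metrics, digits = 3)
cat("\nTasks whose MAE is statistically comparable to the ITV (n.s.):",
    paste(metrics$task[metrics$ns], collapse = ", "), "\n")
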