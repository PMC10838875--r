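#!/usr/bin/env Rscript
# Stage 7 — diagnostic extension: AD vs nAD from FC2 embeddings.
#
# The penultimate-layer activations of every ensemble member feed a
# ridge-penalized logistic regression, a 5-NN classifier and a random forest;
# the final label is a hard majority vote over all member x classifier
# predictions, with AUROC per classifier and for the vote share.

library(cogscan)

volumes <- readRDS("scratch/run/volumes_norm.rds")
subjects <- readRDS("scratch/run/subjects_kept.rds")
ens <- readRDS("scratch/run/ensemble.rds")
seed <- 7L

tr <- subjects$split == "train"
diag <- diagnose_extension(ens,
                           volumes_to_matrix(volumes[tr]),
                           ad_label(subjects$diagnosis[tr]),
                           volumes_to_matrix(volumes[!tr]),
                           ad_label(subjects$diagnosis[!tr]),
                           seed = seed)

jsonlite::write_json(
  list(auroc_per_member = diag$auroc, vote_auroc = diag$vote_auroc,
       vote_accuracy = diag$accuracy),
  "results/diagnosis.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)

cat("AUROC per member x classifier:\n")
print(round(diag$auroc, 3))
cat("Voting ensemble: AUROC", round(diag$vote_auroc, 3),
    "accuracy", round(diag$accuracy, 3), "\n")
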