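#!/usr/bin/env Rscript
# Stage 1 — synthetic desk-scale cohort.
#
# Generates the study's working dataset: a 32^3 atlas with 8 regions, 200
# subjects whose ADAS-Cog13 sub-scores follow a latent severity, volumes with
# one planted region per modelled sub-score (per-voxel effect/noise = 2),
# and a longitudinal visit table for the inter-test-variability benchmark.
# Volumes and tables go to scratch/run/ (large, regenerable); summary tables
# to results/.

library(cogscan)

seed <- 1L
dir.create("results", showWarnings = FALSE)
dir.create("scratch/run", showWarnings = FALSE, recursive = TRUE)

atlas <- make_atlas(c(32, 32, 32), n_regions = 8, seed = seed)
effects <- default_effect_spec(atlas)
cohort <- simulate_cohort(atlas, n_subjects = 200, effects, seed = seed)
visits <- simulate_visits(cohort$subjects, visits_per_subject = 3,
                          fluctuation_sd = 1, seed = seed + 1L)

write_atlas(atlas, "scratch/run/atlas.nii.gz", "results/atlas_regions.tsv")
write.csv(cohort$subjects, "results/subjects.csv", row.names = FALSE)
write.csv(visits, "results/visits.csv", row.names = FALSE)
write.csv(effects$region_effects, "results/planted_effects.csv",
          row.names = FALSE)
saveRDS(cohort, "scratch/run/cohort.rds")
saveRDS(visits, "scratch/run/visits.rds")

cat("Cohort:", length(cohort$volumes), "volumes;",
    "diagnosis counts:", paste(names(table(cohort$subjects$diagnosis)),
                               table(cohort$subjects$diagnosis),
                               collapse = ", "), "\n")
cat("Planted regions:",
    paste(effects$region_effects$score, "->",
          effects$region_effects$region_id, collapse = ", "), "\n")
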