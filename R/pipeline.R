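#' Pipeline configuration
#'
#' Bundles every stage's parameters behind a scale preset. The `desk` preset
#' (32^3 volumes, 8 atlas regions, 4/8/16/32 channels, 64-wide FC layers,
#' 200 subjects) runs the full pipeline in minutes on one CPU; the `full`
#' preset mirrors the full-scale study configuration (112^3 volumes, 56
#' regions, 16/32/64/128 channels, 1024-wide FC layers) and is intended for
#' real cohorts on serious hardware. A single global seed fans out to
#' per-stage seeds as `seed + 1000 * stage_index`, so stages are
#' independently reproducible.
#'
#' @param scale `"desk"` or `"full"`.
#' @param seed global seed.
#' @param stages character vector of stages to run, in pipeline order.
#' @param ... overrides for any configuration entry (e.g. `n_subjects`,
#'   `epochs`, `effect_noise_ratio`, `fill`, `window_days`).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(scale = c("desk", "full"), seed = 1L,
                            stages = c("simulate", "preprocess",
                                       "select_subscores", "train",
                                       "evaluate", "interpret", "diagnose"),
                            ...) {
  scale <- match.arg(scale)
  base <- if (scale == "desk") {
    list(extent = 32L, n_regions = 8L, n_subjects = 200L,
         channels = c(4L, 8L, 16L, 32L), fc_widths = c(64L, 64L),
         epochs = 15L, cycle_length = 15L, lr_max = 0.001)
  } else {
    list(extent = 112L, n_regions = 56L, n_subjects = 2000L,
         channels = c(16L, 32L, 64L, 128L), fc_widths = c(1024L, 1024L),
         epochs = 60L, cycle_length = 10L, lr_max = 0.01)
  }
  cfg <- c(base, list(
    scale = scale, seed = as.integer(seed), stages = stages,
    modality = "MRI",
    tasks = c("q1", "q4", "q7", "q8"),
    effect_noise_ratio = 2, voxel_noise_sd = 10, score_noise_sd = 0.2,
    visits_per_subject = 3L, window_days = 91, fluctuation_sd = 1,
    batch_size = 8L, lr_min = 0.0001,
    k_min = 5L, k_max = 7L, fill = 0, top_k = c(5L, 10L),
    test_fraction = 0.2, qc_tolerance = NULL, alpha = 0.05))
  dots <- list(...)
  cfg[names(dots)] <- dots
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' The file may contain any [pipeline_config()] argument (`scale`, `seed`,
#' `stages`, and overrides such as `n_subjects` or `epochs`).
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$stages)) cfg$stages <- unlist(cfg$stages)
  do.call(pipeline_config, cfg)
}

stage_seed <- function(cfg, stage) {
  idx <- match(stage, c("simulate", "preprocess", "select_subscores", "train",
                        "evaluate", "interpret", "diagnose"))
  as.integer(cfg$seed + 1000L * idx)
}

write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> preprocess -> select-subscores -> train -> evaluate ->
#' interpret -> diagnose in order (skipping stages absent from
#' `config$stages`), writing every stage's outputs and a manifest (config
#' snapshot, per-stage seeds, package version, stage output files) into
#' `run_dir`. Re-running with an identical config reproduces all
#' deterministic outputs.
#'
#' @param config a [pipeline_config()].
#' @param run_dir output directory (created if missing).
#' @param verbose print stage progress.
#' @return list with the in-memory stage results and the manifest, invisibly.
#' @export
run_pipeline <- function(config, run_dir = tempfile("cogscan_run_"),
                         verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[", format(Sys.time(), "%H:%M:%S"),
                                            "] ", ...)
  manifest <- list(package_version = as.character(utils::packageVersion("cogscan")),
                   config = config[setdiff(names(config), "stages")],
                   stages_run = list(), outputs = list())
  res <- list()

  ## simulate ----------------------------------------------------------------
  s <- stage_seed(config, "simulate")
  say("simulate (seed ", s, ")")
  atlas <- make_atlas(rep(config$extent, 3), config$n_regions, seed = s)
  effects <- default_effect_spec(atlas, tasks = config$tasks,
                                 effect_noise_ratio = config$effect_noise_ratio,
                                 voxel_noise_sd = config$voxel_noise_sd,
                                 score_noise_sd = config$score_noise_sd,
                                 visit_sd = config$fluctuation_sd)
  cohort <- simulate_cohort(atlas, config$n_subjects, effects,
                            modality = config$modality,
                            test_fraction = config$test_fraction, seed = s)
  visits <- simulate_visits(cohort$subjects, config$visits_per_subject,
                            config$window_days, config$fluctuation_sd,
                            seed = s + 1L)
  res$cohort <- cohort; res$visits <- visits; res$effects <- effects
  write.csv(cohort$subjects, file.path(run_dir, "subjects.csv"),
            row.names = FALSE)
  write.csv(visits, file.path(run_dir, "visits.csv"), row.names = FALSE)
  write_atlas(atlas, file.path(run_dir, "atlas.nii.gz"),
              file.path(run_dir, "atlas_regions.tsv"))
  manifest$outputs$simulate <- c("subjects.csv", "visits.csv", "atlas.nii.gz",
                                 "atlas_regions.tsv")
  manifest$stages_run$simulate <- s
  manifest$planted_regions <- stats::setNames(
    as.list(effects$region_effects$region_id), effects$region_effects$score)

  ## preprocess --------------------------------------------------------------
  if ("preprocess" %in% config$stages) {
    s <- stage_seed(config, "preprocess")
    say("preprocess (white-stripe, modality ", config$modality, ")")
    ref <- ws_reference()
    tol <- if (is.null(config$qc_tolerance)) 0.5 * ref$sigma_ref
           else config$qc_tolerance
    if (config$modality == "MRI") {
      norm <- lapply(cohort$volumes, white_stripe_normalize, ref = ref)
      qc <- lapply(norm, qc_white_stripe, ref = ref, tolerance = tol)
      qc_df <- data.frame(
        subject_id = vapply(qc, `[[`, character(1), "subject_id"),
        deviation = vapply(qc, `[[`, numeric(1), "deviation"),
        pass = vapply(qc, `[[`, logical(1), "pass"))
      write.csv(qc_df, file.path(run_dir, "qc_white_stripe.csv"),
                row.names = FALSE)
      keep <- qc_df$pass
      if (any(!keep)) say(sum(!keep), " volume(s) failed white-stripe QC; excluded")
      res$volumes <- norm[keep]
      res$subjects <- cohort$subjects[keep, , drop = FALSE]
      manifest$outputs$preprocess <- "qc_white_stripe.csv"
    } else {
      tr <- cohort$subjects$split == "train"
      cn <- cohort_normalize_pet(cohort$volumes[tr], cohort$volumes)
      res$volumes <- cn$volumes
      res$subjects <- cohort$subjects
      write_json(cn$stats, file.path(run_dir, "pet_norm_stats.json"))
      manifest$outputs$preprocess <- "pet_norm_stats.json"
    }
    manifest$stages_run$preprocess <- s
  } else {
    res$volumes <- cohort$volumes
    res$subjects <- cohort$subjects
  }
  subjects <- res$subjects

  ## select-subscores ---------------------------------------------------------
  if ("select_subscores" %in% config$stages) {
    s <- stage_seed(config, "select_subscores")
    say("select-subscores (random forest)")
    scaled <- minmax_scale(subjects, cohort$scales)
    scaled$label <- ad_label(subjects$diagnosis)
    sp <- balance_and_split(scaled, config$test_fraction, seed = s)
    sel <- select_top_subscores(sp$train, sp$test, seed = s,
                                k = length(config$tasks))
    res$selection <- sel
    write_json(list(importance = as.list(sel$importance),
                    top_k = sel$top_k, metrics = as.list(sel$metrics)),
               file.path(run_dir, "subscore_selection.json"))
    manifest$outputs$select_subscores <- "subscore_selection.json"
    manifest$stages_run$select_subscores <- s
  }

  ## train --------------------------------------------------------------------
  if ("train" %in% config$stages) {
    s <- stage_seed(config, "train")
    say("train (", config$epochs, " epochs)")
    tr <- subjects$split == "train"
    x_tr <- volumes_to_matrix(res$volumes[tr])
    x_te <- volumes_to_matrix(res$volumes[!tr])
    y_tr <- scale_targets(subjects[tr, ], config$tasks, cohort$scales)
    y_te <- scale_targets(subjects[!tr, ], config$tasks, cohort$scales)
    mcfg <- cnn_model_config(extent = config$extent,
                             channels = config$channels,
                             fc_widths = config$fc_widths,
                             n_tasks = length(config$tasks),
                             batch_size = config$batch_size,
                             lr_max = config$lr_max, lr_min = config$lr_min,
                             cycle_length = config$cycle_length,
                             epochs = config$epochs)
    model <- build_cnn(mcfg, seed = s)
    cps <- train_cnn(model, x_tr, y_tr, x_te, y_te, seed = s + 1L,
                     verbose = verbose)
    ens <- select_ensemble(cps, mcfg, cohort$scales, config$tasks,
                           config$k_min, config$k_max)
    res$ensemble <- ens
    res$train_idx <- which(tr); res$test_idx <- which(!tr)
    hist <- data.frame(epoch = vapply(cps, `[[`, numeric(1), "epoch"),
                       train_loss = vapply(cps, `[[`, numeric(1), "train_loss"),
                       test_mse = vapply(cps, `[[`, numeric(1), "test_mse"))
    write.csv(hist, file.path(run_dir, "training_history.csv"),
              row.names = FALSE)
    manifest$outputs$train <- "training_history.csv"
    manifest$stages_run$train <- s
    manifest$ensemble <- list(
      members = vapply(ens$members, `[[`, numeric(1), "epoch"),
      k_min = config$k_min, k_max = config$k_max)
  }

  ## evaluate -----------------------------------------------------------------
  if ("evaluate" %in% config$stages && !is.null(res$ensemble)) {
    s <- stage_seed(config, "evaluate")
    say("evaluate (MAE, R2, ITV)")
    te <- res$test_idx
    y_raw <- as.matrix(subjects[te, config$tasks])
    pred <- predict(res$ensemble, res$volumes[te],
                    subject_ids = subjects$subject_id[te], y_true = y_raw)
    res$predictions <- pred
    metrics <- evaluate_predictions(pred, visits, config$window_days,
                                    config$alpha)
    res$metrics <- metrics
    write.csv(pred, file.path(run_dir, "predictions.csv"), row.names = FALSE)
    write_json(metrics, file.path(run_dir, "metrics.json"))
    manifest$outputs$evaluate <- c("predictions.csv", "metrics.json")
    manifest$stages_run$evaluate <- s
  }

  ## interpret ----------------------------------------------------------------
  if ("interpret" %in% config$stages && !is.null(res$ensemble)) {
    s <- stage_seed(config, "interpret")
    say("interpret (occlusion importance, fill ", config$fill, ")")
    te <- res$test_idx
    y_raw <- as.matrix(subjects[te, config$tasks])
    imp <- importance_table(res$ensemble, res$volumes[te], y_raw,
                            cohort$atlas, tasks = config$tasks,
                            subgroups = subjects$diagnosis[te],
                            fill = config$fill)
    res$importance <- imp
    corr <- subscore_correlation(imp, alpha = config$alpha)
    res$correlation <- corr
    write.csv(imp, file.path(run_dir, "importance.csv"), row.names = FALSE)
    write.csv(as.data.frame(corr$rho),
              file.path(run_dir, "subscore_correlation.csv"))
    write_json(list(rho = corr$rho, p_adj = corr$p_adj),
               file.path(run_dir, "subscore_correlation.json"))
    manifest$outputs$interpret <- c("importance.csv",
                                    "subscore_correlation.csv",
                                    "subscore_correlation.json")
    manifest$stages_run$interpret <- s
  }

  ## diagnose -----------------------------------------------------------------
  if ("diagnose" %in% config$stages && !is.null(res$ensemble)) {
    s <- stage_seed(config, "diagnose")
    say("diagnose (FC2 embeddings -> LR/KNN/RF vote)")
    tr <- res$train_idx; te <- res$test_idx
    diag <- diagnose_extension(res$ensemble,
                               volumes_to_matrix(res$volumes[tr]),
                               ad_label(subjects$diagnosis[tr]),
                               volumes_to_matrix(res$volumes[te]),
                               ad_label(subjects$diagnosis[te]),
                               seed = s)
    res$diagnosis <- diag
    write_json(list(auroc = diag$auroc, vote_auroc = diag$vote_auroc,
                    accuracy = diag$accuracy),
               file.path(run_dir, "diagnosis.json"))
    manifest$outputs$diagnose <- "diagnosis.json"
    manifest$stages_run$diagnose <- s
  }

  write_json(manifest, file.path(run_dir, "manifest.json"))
  say("done: ", run_dir)
  res$manifest <- manifest
  res$run_dir <- run_dir
  invisible(res)
}
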