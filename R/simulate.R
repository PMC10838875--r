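#' Brain volume container
#'
#' A minimal container for one subject's co-registered, skull-stripped 3D
#' intensity grid: the voxel data, an imaging-modality tag and the voxel
#' geometry.
#'
#' @param data 3D numeric array of voxel intensities (finite).
#' @param modality one of `"MRI"`, `"FDG-PET"`, `"AV45-PET"`.
#' @param spacing voxel spacing in mm (length 3).
#' @param subject_id optional subject identifier.
#' @return An object of class `brain_volume`.
#' @export
brain_volume <- function(data, modality = c("MRI", "FDG-PET", "AV45-PET"),
                         spacing = c(1, 1, 1), subject_id = NA_character_) {
  modality <- match.arg(modality)
  if (length(dim(data)) != 3L) stop("volume data must be a 3D array")
  if (!all(is.finite(data))) stop("volume intensities must be finite")
  structure(list(data = data, modality = modality,
                 spacing = as.numeric(spacing),
                 subject_id = subject_id),
            class = "brain_volume")
}

#' @export
print.brain_volume <- function(x, ...) {
  cat("brain_volume:", paste(dim(x$data), collapse = "x"), x$modality,
      "subject", x$subject_id, "\n")
  invisible(x)
}

#' Conventional ADAS-Cog13 sub-score scales
#'
#' Per-item `[min, max]` ranges for the 13 sub-scores. Item ranges follow the
#' conventional ADAS-Cog13 scoring (word recall and delayed word recall 0-10,
#' orientation 0-8, word recognition 0-12, remaining items 0-5). These are
#' configuration, not constants: every function taking scores also takes a
#' scales table.
#'
#' @return data.frame with columns `score`, `min`, `max` (13 rows).
#' @export
adas_scales <- function() {
  data.frame(
    score = paste0("q", 1:13),
    min = rep(0, 13),
    max = c(10, 5, 5, 10, 5, 5, 8, 12, 5, 5, 5, 5, 5),
    stringsAsFactors = FALSE)
}

score_cols <- function() paste0("q", 1:13)

#' Effect specification for the synthetic cohort generator
#'
#' Describes the planted generative structure: which atlas region carries
#' which sub-score's signal (and how strongly), the voxel noise, the
#' sub-score measurement noise, the visit-to-visit fluctuation, and the
#' severity loading of each sub-score.
#'
#' The planted voxel signal for a region/score pair is
#' `effect * s` intensity units, where `s` in `[0, 1]` is the subject's
#' recorded sub-score on its min-max scale. `effect / voxel_noise_sd` is the
#' per-voxel effect-to-noise ratio.
#'
#' @param region_effects data.frame with columns `region_id`, `score`,
#'   `effect` (intensity units per unit of scaled score).
#' @param voxel_noise_sd Gaussian voxel noise sd (intensity units).
#' @param score_noise_sd per-sub-score measurement noise sd, on the scaled
#'   `[0, 1]` axis.
#' @param visit_sd visit-to-visit score fluctuation sd, raw score units.
#' @param loadings named vector of severity loadings per sub-score
#'   (`q1`..`q13`); scores with loading 0 are pure noise. Defaults to loading
#'   1 on q1, q4, q7, q8 (the diagnosis-relevant items) and 0 elsewhere.
#' @param severity_slope scaled-score units per unit latent severity.
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(region_effects,
                        voxel_noise_sd = 10,
                        score_noise_sd = 0.2,
                        visit_sd = 1,
                        loadings = NULL,
                        severity_slope = 0.2) {
  stopifnot(is.data.frame(region_effects),
            all(c("region_id", "score", "effect") %in% names(region_effects)))
  if (voxel_noise_sd < 0 || score_noise_sd < 0 || visit_sd < 0)
    stop("noise standard deviations must be >= 0")
  if (is.null(loadings)) {
    loadings <- stats::setNames(rep(0, 13), score_cols())
    loadings[c("q1", "q4", "q7", "q8")] <- 1
  }
  if (!all(names(loadings) %in% score_cols()))
    stop("loadings must be named by sub-score q1..q13")
  full <- stats::setNames(rep(0, 13), score_cols())
  full[names(loadings)] <- loadings
  structure(list(region_effects = region_effects,
                 voxel_noise_sd = voxel_noise_sd,
                 score_noise_sd = score_noise_sd,
                 visit_sd = visit_sd,
                 loadings = full,
                 severity_slope = severity_slope),
            class = "effect_spec")
}

#' Default planted-effect specification for an atlas
#'
#' Plants one region per modelled task (q1, q4, q7, q8 by default), spacing
#' the planted regions evenly across the atlas, each with the requested
#' per-voxel effect-to-noise ratio.
#'
#' @param atlas an `atlas_parcellation`.
#' @param tasks sub-scores to plant (each gets one region).
#' @param effect_noise_ratio per-voxel effect size over voxel noise sd.
#' @param voxel_noise_sd Gaussian voxel noise sd.
#' @param ... further arguments passed to [effect_spec()].
#' @return An `effect_spec`.
#' @export
default_effect_spec <- function(atlas, tasks = c("q1", "q4", "q7", "q8"),
                                effect_noise_ratio = 2, voxel_noise_sd = 10,
                                ...) {
  k <- nrow(atlas$regions)
  if (k < length(tasks))
    stop("atlas must have at least ", length(tasks), " regions")
  ids <- unique(round(seq(k / length(tasks), k, length.out = length(tasks))))
  re <- data.frame(region_id = ids, score = tasks,
                   effect = effect_noise_ratio * voxel_noise_sd,
                   stringsAsFactors = FALSE)
  effect_spec(re, voxel_noise_sd = voxel_noise_sd, ...)
}

# Diagnosis class cut-points: latent severity quantiles chosen to mirror the
# roughly 1/3 CN, 45% MCI, 22% AD composition of large AD research cohorts.
diagnosis_cuts <- function() qnorm(c(0.336, 0.783))

assign_diagnosis <- function(severity) {
  cuts <- diagnosis_cuts()
  factor(ifelse(severity < cuts[1], "CN",
                ifelse(severity < cuts[2], "MCI", "AD")),
         levels = c("CN", "MCI", "AD"))
}

#' Simulate subject records (sub-scores, diagnosis, split)
#'
#' Draws a latent per-subject severity from a standard normal; each sub-score
#' is a monotone (linear, clipped) function of severity plus Gaussian
#' measurement noise on its min-max scale; diagnosis is assigned by
#' thresholding severity at fixed quantiles (equivalently, by thresholding the
#' expected total score, which is strictly monotone in severity); subjects are
#' split train/test at the configured ratio.
#'
#' @param n_subjects number of subjects.
#' @param effects an `effect_spec` (provides loadings and score noise).
#' @param scales per-score `[min, max]` table, see [adas_scales()].
#' @param test_fraction held-out fraction (default 0.2 for an 80:20 split).
#' @param seed integer seed.
#' @return data.frame with `subject_id`, `severity`, `diagnosis`, `split`,
#'   and raw sub-scores `q1..q13` (each within its declared range).
#' @export
simulate_subscores <- function(n_subjects, effects = NULL,
                               scales = adas_scales(), test_fraction = 0.2,
                               seed = 1L) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (is.null(effects))
    effects <- effect_spec(data.frame(region_id = integer(), score = character(),
                                      effect = numeric()))
  with_seed(seed, {
    severity <- rnorm(n_subjects)
    scaled <- matrix(NA_real_, n_subjects, 13,
                     dimnames = list(NULL, score_cols()))
    for (j in seq_len(13)) {
      s <- score_cols()[j]
      u <- 0.5 + effects$severity_slope * effects$loadings[s] * severity +
        rnorm(n_subjects, 0, effects$score_noise_sd)
      scaled[, j] <- pmin(1, pmax(0, u))
    }
    raw <- sweep(scaled, 2, scales$max - scales$min, `*`)
    raw <- sweep(raw, 2, scales$min, `+`)
    n_test <- round(test_fraction * n_subjects)
    split <- rep("train", n_subjects)
    split[sample.int(n_subjects, n_test)] <- "test"
    out <- data.frame(subject_id = sprintf("S%04d", seq_len(n_subjects)),
                      severity = severity,
                      diagnosis = assign_diagnosis(severity),
                      split = split, stringsAsFactors = FALSE)
    cbind(out, as.data.frame(raw))
  })
}

#' Simulate a synthetic brain cohort (volumes + subject records)
#'
#' Generates subject records with [simulate_subscores()], then one volume per
#' subject: brain voxels get a modality-specific baseline plus, for every
#' planted (region, sub-score) pair, `effect * scaled score` in that region,
#' plus i.i.d. Gaussian voxel noise. Background voxels are 0. Generation is
#' seed-reproducible.
#'
#' @param atlas an `atlas_parcellation`.
#' @param n_subjects number of subjects.
#' @param effects an `effect_spec`; region ids must exist in the atlas.
#' @param modality imaging modality tag for the volumes.
#' @param scales per-score scale table.
#' @param test_fraction held-out fraction.
#' @param seed integer seed.
#' @param baseline brain-tissue baseline intensity; default depends on
#'   modality (100 for MRI, 6 for FDG-PET, 1.5 for AV45-PET).
#' @return list with `volumes` (list of `brain_volume`), `subjects`
#'   (data.frame), `scales`, and the `atlas`.
#' @export
simulate_cohort <- function(atlas, n_subjects, effects,
                            modality = c("MRI", "FDG-PET", "AV45-PET"),
                            scales = adas_scales(), test_fraction = 0.2,
                            seed = 1L, baseline = NULL) {
  modality <- match.arg(modality)
  stopifnot(inherits(atlas, "atlas_parcellation"),
            inherits(effects, "effect_spec"))
  bad <- setdiff(effects$region_effects$region_id, atlas$regions$region_id)
  if (length(bad))
    stop("effect map references regions absent from the atlas: ",
         paste(bad, collapse = ", "))
  if (is.null(baseline))
    baseline <- c("MRI" = 100, "FDG-PET" = 6, "AV45-PET" = 1.5)[[modality]]
  subjects <- simulate_subscores(n_subjects, effects, scales,
                                 test_fraction, seed)
  smin <- stats::setNames(scales$min, scales$score)
  smax <- stats::setNames(scales$max, scales$score)
  dims <- dim(atlas$labels)
  brain <- atlas$labels > 0L
  masks <- lapply(effects$region_effects$region_id,
                  function(r) atlas$labels == r)
  volumes <- with_seed(seed + 1L, lapply(seq_len(n_subjects), function(i) {
    arr <- array(0, dim = dims)
    arr[brain] <- baseline + rnorm(sum(brain), 0, effects$voxel_noise_sd)
    if (nrow(effects$region_effects)) {
      for (e in seq_len(nrow(effects$region_effects))) {
        sc <- effects$region_effects$score[e]
        s01 <- (subjects[[sc]][i] - smin[[sc]]) / (smax[[sc]] - smin[[sc]])
        arr[masks[[e]]] <- arr[masks[[e]]] +
          effects$region_effects$effect[e] * s01
      }
    }
    brain_volume(arr, modality, subject_id = subjects$subject_id[i])
  }))
  list(volumes = volumes, subjects = subjects, scales = scales, atlas = atlas)
}

#' Simulate a longitudinal visit table
#'
#' Gives each subject dated repeat visits scattered uniformly inside a
#' +/- `window_days` window around a per-subject anchor date; at every visit
#' each sub-score is the subject's base score plus a Gaussian fluctuation of
#' the given sd, clipped to its scale. Dates are emitted as ISO-8601 strings.
#'
#' @param subjects data.frame from [simulate_subscores()] (needs
#'   `subject_id` and `q1..q13`).
#' @param visits_per_subject number of visits per subject (>= 1).
#' @param window_days half-width of the visit window in days.
#' @param fluctuation_sd per-score fluctuation sd in raw score units; scalar
#'   or named vector over `q1..q13`.
#' @param scales per-score scale table (for clipping).
#' @param seed integer seed.
#' @return data.frame with `subject_id`, `visit_date` (ISO-8601 character),
#'   and `q1..q13`.
#' @export
simulate_visits <- function(subjects, visits_per_subject = 3,
                            window_days = 91, fluctuation_sd = 1,
                            scales = adas_scales(), seed = 1L) {
  if (visits_per_subject < 1) stop("visits_per_subject must be >= 1")
  if (any(fluctuation_sd < 0)) stop("fluctuation_sd must be >= 0")
  sds <- stats::setNames(rep(0, 13), score_cols())
  if (is.null(names(fluctuation_sd))) {
    sds[] <- fluctuation_sd
  } else {
    sds[names(fluctuation_sd)] <- fluctuation_sd
  }
  n <- nrow(subjects)
  with_seed(seed, {
    anchor <- as.Date("2024-01-01") + sample.int(365, n, replace = TRUE) - 1L
    rows <- lapply(seq_len(n), function(i) {
      offs <- round(runif(visits_per_subject, -window_days, window_days))
      offs[1] <- 0  # the anchor visit itself
      sc <- matrix(NA_real_, visits_per_subject, 13,
                   dimnames = list(NULL, score_cols()))
      for (j in seq_len(13)) {
        s <- score_cols()[j]
        v <- subjects[[s]][i] + rnorm(visits_per_subject, 0, sds[s])
        sc[, j] <- pmin(scales$max[j], pmax(scales$min[j], v))
      }
      data.frame(subject_id = subjects$subject_id[i],
                 visit_date = format(anchor[i] + offs, "%Y-%m-%d"),
                 sc, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
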