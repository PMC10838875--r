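#' White-stripe reference distribution
#'
#' Fixed target mean and standard deviation for the normal-appearing white
#' matter (NAWM) intensity distribution after white-stripe normalization, plus
#' the stripe half-width (quantile fraction around the NAWM mode used to
#' estimate the stripe).
#'
#' @param mu_ref reference NAWM mean, intensity units.
#' @param sigma_ref reference NAWM sd, intensity units (> 0).
#' @param half_width quantile half-width of the stripe, in (0, 0.5).
#' @return An object of class `ws_reference`.
#' @export
ws_reference <- function(mu_ref = 0, sigma_ref = 1, half_width = 0.05) {
  if (sigma_ref <= 0) stop("sigma_ref must be > 0")
  if (half_width <= 0 || half_width >= 0.5)
    stop("half_width must be in (0, 0.5)")
  structure(list(mu_ref = mu_ref, sigma_ref = sigma_ref,
                 half_width = half_width),
            class = "ws_reference")
}

brain_values <- function(volume) {
  v <- as.vector(volume$data)
  v[v != 0]  # volumes are brain-masked upstream; background is exactly 0
}

#' Estimate the normal-appearing white matter stripe
#'
#' Finds the dominant high-intensity mode of the brain-voxel histogram by
#' kernel-density peak picking (the NAWM peak on T1 MRI: among density peaks
#' of substantial height, the one at the highest intensity), then takes the
#' "stripe" of voxels between the `tau - half_width` and `tau + half_width`
#' intensity quantiles, where `tau` is the quantile of the mode.
#'
#' @param volume an MRI `brain_volume` (masked; background 0).
#' @param half_width stripe half-width as a quantile fraction.
#' @param peak_frac minimum density of a candidate peak, as a fraction of the
#'   global density maximum.
#' @return list with `mode` (intensity), `sd` (stripe sd), `mask` (logical
#'   array over the grid), `tau` (mode quantile).
#' @export
estimate_nawm <- function(volume, half_width = 0.05, peak_frac = 1 / 3) {
  if (volume$modality != "MRI")
    stop("NAWM estimation is defined for MRI volumes")
  v <- brain_values(volume)
  if (length(unique(v)) < 2L)
    stop("degenerate input: volume has no intensity variation")
  d <- density(v, n = 2048)
  y <- d$y
  peaks <- which(diff(sign(diff(y))) == -2) + 1L
  if (!length(peaks)) peaks <- which.max(y)
  peaks <- peaks[y[peaks] >= peak_frac * max(y)]
  if (!length(peaks))
    stop("degenerate input: no detectable NAWM mode")
  mode <- d$x[max(peaks)]  # highest-intensity qualifying peak
  tau <- mean(v <= mode)
  lo <- quantile(v, max(0, tau - half_width), names = FALSE)
  hi <- quantile(v, min(1, tau + half_width), names = FALSE)
  mask <- volume$data >= lo & volume$data <= hi & volume$data != 0
  stripe <- volume$data[mask]
  if (length(stripe) < 2L || sd(stripe) == 0)
    stop("degenerate input: NAWM stripe has zero spread")
  list(mode = mode, sd = sd(stripe), mask = mask, tau = tau)
}

#' White-stripe intensity normalization
#'
#' Affine transform of the brain voxels matching the volume's NAWM
#' distribution to the reference: `(x - mode) / sd * sigma_ref + mu_ref`.
#' Background voxels (exactly 0) stay 0, the background value in normalized
#' units.
#'
#' @param volume an MRI `brain_volume`.
#' @param ref a [ws_reference()].
#' @return The normalized `brain_volume`, with the estimated `mode` and `sd`
#'   attached as attribute `nawm`.
#' @export
white_stripe_normalize <- function(volume, ref = ws_reference()) {
  est <- estimate_nawm(volume, ref$half_width)
  brain <- volume$data != 0
  volume$data[brain] <- (volume$data[brain] - est$mode) / est$sd *
    ref$sigma_ref + ref$mu_ref
  attr(volume, "nawm") <- list(mode = est$mode, sd = est$sd)
  volume
}

#' Quality control of white-stripe normalization
#'
#' Re-estimates the NAWM mode of a normalized volume and fails the volume when
#' the mode deviates from `mu_ref` by more than `tolerance` (inclusive bound:
#' a deviation exactly at the tolerance passes). Failed volumes are flagged
#' for exclusion from downstream modelling.
#'
#' @param normalized a white-stripe-normalized MRI `brain_volume`.
#' @param ref the [ws_reference()] used for normalization.
#' @param tolerance maximum allowed |mode - mu_ref|; default `0.5 * sigma_ref`.
#' @return list with `pass` (logical), `deviation`, `mode`, `tolerance`,
#'   `subject_id`.
#' @export
qc_white_stripe <- function(normalized, ref = ws_reference(),
                            tolerance = 0.5 * ref$sigma_ref) {
  est <- estimate_nawm(normalized, ref$half_width)
  dev <- abs(est$mode - ref$mu_ref)
  list(pass = dev <= tolerance, deviation = dev, mode = est$mode,
       tolerance = tolerance, subject_id = normalized$subject_id)
}

#' Cohort intensity normalization for PET volumes
#'
#' Computes, for every training volume, the brain-voxel intensity at the
#' 99.9th percentile (`n_stats`; linear interpolation between order
#' statistics), then divides every volume by the maximum `n_stats` over the
#' training cohort, so training-cohort voxels at or below their per-image
#' `n_stats` land in `[0, 1]`. Values above the divisor are retained
#' unclipped (the range constraint holds at the cohort level, for the
#' training cohort); such volumes are reported in the returned stats.
#'
#' @param train_volumes non-empty list of PET `brain_volume`s defining the
#'   divisor.
#' @param apply_volumes volumes to scale (default: the training volumes).
#' @param probs percentile used for `n_stats` (default 0.999).
#' @return list with `volumes` (scaled `apply_volumes`) and `stats` (list with
#'   per-image `n_stats`, the `divisor`, and `n_exceeding`, the count of
#'   scaled volumes containing values above 1).
#' @export
cohort_normalize_pet <- function(train_volumes, apply_volumes = train_volumes,
                                 probs = 0.999) {
  if (!length(train_volumes)) stop("training cohort is empty")
  mods <- vapply(train_volumes, function(v) v$modality, character(1))
  if (any(!mods %in% c("FDG-PET", "AV45-PET")))
    stop("cohort normalization is defined for PET volumes")
  n_stats <- vapply(train_volumes,
                    function(v) quantile(brain_values(v), probs,
                                         names = FALSE, type = 7),
                    numeric(1))
  divisor <- max(n_stats)
  if (divisor <= 0) stop("degenerate input: non-positive divisor")
  scaled <- lapply(apply_volumes, function(v) {
    v$data <- v$data / divisor
    v
  })
  n_exceed <- sum(vapply(scaled, function(v) any(v$data > 1), logical(1)))
  if (n_exceed > 0)
    message(n_exceed, " volume(s) contain values above 1 after scaling ",
            "(retained unclipped)")
  list(volumes = scaled,
       stats = list(n_stats = n_stats, divisor = divisor,
                    n_exceeding = n_exceed))
}
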