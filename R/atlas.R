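#' Synthetic atlas parcellation
#'
#' Builds an integer-labelled parcellation of a cubic grid: the brain mask is
#' a centred ellipsoid and its voxels are partitioned into `n_regions`
#' contiguous regions by nearest-seed-voxel assignment. Label 0 is background
#' (non-brain). Region ids are contiguous `1..n_regions` and every region is
#' non-empty. At full scale a real analysis would use a published structural
#' atlas with 56 cortical and subcortical regions; this generator stands in
#' for it so the pipeline is testable without external data.
#'
#' @param grid_shape integer vector of length 3, grid extents.
#' @param n_regions number of regions (>= 1).
#' @param seed integer seed; identical arguments give identical label grids.
#' @param axes_frac semi-axes of the ellipsoid as a fraction of each extent.
#' @return An object of class `atlas_parcellation`: list with `labels`
#'   (3D integer array) and `regions` (data.frame `region_id`, `region_name`).
#' @export
make_atlas <- function(grid_shape, n_regions, seed = 1L, axes_frac = 0.45) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 2))
  if (n_regions < 1) stop("n_regions must be >= 1")
  dims <- as.integer(grid_shape)
  ctr <- (dims + 1) / 2
  ax <- axes_frac * dims
  g <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                   z = seq_len(dims[3]))
  inside <- ((g$x - ctr[1]) / ax[1])^2 + ((g$y - ctr[2]) / ax[2])^2 +
    ((g$z - ctr[3]) / ax[3])^2 <= 1
  n_brain <- sum(inside)
  if (n_brain < n_regions)
    stop("grid too small to host ", n_regions, " non-empty regions")
  labels <- integer(prod(dims))
  if (n_regions == 1L) {
    labels[inside] <- 1L
  } else {
    coords <- cbind(g$x, g$y, g$z)[inside, , drop = FALSE]
    seeds <- with_seed(seed, coords[sample.int(n_brain, n_regions), , drop = FALSE])
    # nearest-seed assignment (squared Euclidean in voxel units)
    d2 <- matrix(0, nrow = n_brain, ncol = n_regions)
    for (k in seq_len(n_regions))
      d2[, k] <- (coords[, 1] - seeds[k, 1])^2 +
        (coords[, 2] - seeds[k, 2])^2 + (coords[, 3] - seeds[k, 3])^2
    labels[inside] <- max.col(-d2, ties.method = "first")
  }
  labels <- array(labels, dim = dims)
  regions <- data.frame(
    region_id = seq_len(n_regions),
    region_name = sprintf("region_%02d", seq_len(n_regions)),
    stringsAsFactors = FALSE)
  structure(list(labels = labels, regions = regions),
            class = "atlas_parcellation")
}

#' @export
print.atlas_parcellation <- function(x, ...) {
  cat("atlas_parcellation:", paste(dim(x$labels), collapse = "x"),
      "grid,", nrow(x$regions), "regions,",
      sum(x$labels > 0L), "brain voxels\n")
  invisible(x)
}

#' Apply a brain mask to a volume
#'
#' Sets every voxel whose atlas label is 0 (background / non-brain) to the
#' background value; brain voxels are untouched.
#'
#' @param volume a `brain_volume`.
#' @param atlas an `atlas_parcellation` of the same grid shape.
#' @param background value written to non-brain voxels (0 by convention in
#'   normalized units).
#' @return The masked `brain_volume`.
#' @export
apply_brain_mask <- function(volume, atlas, background = 0) {
  check_geometry(volume, atlas)
  volume$data[atlas$labels == 0L] <- background
  volume
}

#' Occlude one atlas region in a volume
#'
#' Replaces every voxel of the given region with `fill`, leaving all other
#' voxels bit-identical. This is the input perturbation underlying the
#' occlusion importance score.
#'
#' @param volume a `brain_volume`.
#' @param atlas an `atlas_parcellation` of matching shape.
#' @param region_id region to occlude; must exist in the atlas table.
#' @param fill replacement intensity (default 0, the background value in
#'   normalized units).
#' @return The occluded `brain_volume`.
#' @export
occlude_region <- function(volume, atlas, region_id, fill = 0) {
  check_geometry(volume, atlas)
  if (!region_id %in% atlas$regions$region_id)
    stop("unknown region_id: ", region_id)
  volume$data[atlas$labels == region_id] <- fill
  volume
}

check_geometry <- function(volume, atlas) {
  if (!identical(dim(volume$data), dim(atlas$labels)))
    stop("volume and atlas grid shapes differ (",
         paste(dim(volume$data), collapse = "x"), " vs ",
         paste(dim(atlas$labels), collapse = "x"), ")")
  invisible(TRUE)
}

#' Mean intensity per atlas region
#'
#' @param volume a `brain_volume`.
#' @param atlas an `atlas_parcellation`.
#' @return named numeric vector, one mean per region id.
#' @export
region_means <- function(volume, atlas) {
  check_geometry(volume, atlas)
  lab <- as.vector(atlas$labels)
  keep <- lab > 0L
  m <- tapply(as.vector(volume$data)[keep], lab[keep], mean)
  out <- rep(NA_real_, nrow(atlas$regions))
  names(out) <- atlas$regions$region_id
  out[names(m)] <- m
  out
}
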