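#' Read a brain volume from NIfTI-1
#'
#' @param path NIfTI file path.
#' @param modality modality tag to attach.
#' @param subject_id subject identifier to attach.
#' @return A `brain_volume` (intensities, voxel spacing from the header).
#' @export
read_volume <- function(path, modality = "MRI", subject_id = NA_character_) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("expected a 3D volume, got ", length(dim(img)), "D: ", path)
  arr <- array(as.numeric(img), dim = dim(img))  # plain array, no header attrs
  brain_volume(arr, modality = modality,
               spacing = RNifti::pixdim(img)[seq_len(3)],
               subject_id = subject_id)
}

#' Write a brain volume to NIfTI-1
#'
#' @param volume a `brain_volume`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  arr <- volume$data
  attr(arr, "pixdim") <- volume$spacing
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "double"), path)
  invisible(path)
}

#' Write an atlas parcellation (integer NIfTI + region table TSV)
#'
#' @param atlas an `atlas_parcellation`.
#' @param nifti_path path for the integer label volume.
#' @param tsv_path path for the two-column region table.
#' @return `nifti_path`, invisibly.
#' @export
write_atlas <- function(atlas, nifti_path, tsv_path) {
  img <- RNifti::asNifti(atlas$labels, datatype = "int16")
  RNifti::writeNifti(img, nifti_path)
  utils::write.table(atlas$regions, tsv_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(nifti_path)
}

#' Read an atlas parcellation written by [write_atlas()]
#'
#' Labels are read as integers and never interpolated.
#'
#' @param nifti_path label volume path.
#' @param tsv_path region table path.
#' @return An `atlas_parcellation`.
#' @export
read_atlas <- function(nifti_path, tsv_path) {
  img <- RNifti::readNifti(nifti_path)
  labels <- array(as.integer(round(as.array(img))), dim = dim(img))
  regions <- utils::read.delim(tsv_path, stringsAsFactors = FALSE)
  lab <- sort(unique(labels[labels > 0L]))
  if (!all(lab %in% regions$region_id))
    stop("atlas labels missing from region table: ",
         paste(setdiff(lab, regions$region_id), collapse = ", "))
  structure(list(labels = labels, regions = regions),
            class = "atlas_parcellation")
}
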