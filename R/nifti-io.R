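# NIfTI I/O.  On disk the affine follows the NIfTI RAS+ convention; in
# memory all geometry is LPS, so the first two affine rows change sign on
# the way in and out.

ras_flip <- diag(c(-1, -1, 1))

#' Read a 3D volume from a NIfTI file
#'
#' The file's affine must encode an orthonormal, non-flipped voxel-to-world
#' rotation (direction-cosine determinant +1 after the RAS-to-LPS
#' conversion); anything else is rejected rather than silently reoriented.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param modality modality label to attach; if `NULL` (default) the label
#'   stored in the file's `intent_name`/`descrip` field is used when
#'   present, else `"CT"`.
#' @return An [image_volume()] (a [binary_mask()] if the modality resolves
#'   to `"MASK"`).
#' @export
read_volume <- function(path, modality = NULL) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop(sprintf("expected a 3D image, got %dD: %s",
                 length(dim(img)), path), call. = FALSE)
  aff <- RNifti::xform(img)           # voxel -> RAS mm
  aff_lps <- ras_flip %*% matrix(aff[1:3, 1:4], 3, 4)
  M <- aff_lps[, 1:3, drop = FALSE]
  spacing <- sqrt(colSums(M^2))
  if (any(spacing <= 0))
    stop("invalid NIfTI affine: zero-length axis", call. = FALSE)
  direction <- sweep(M, 2, spacing, `/`)
  ok <- tryCatch({ check_direction(direction); TRUE },
                 error = function(e) FALSE)
  if (!ok)
    stop(sprintf("NIfTI affine is not an orthonormal right-handed rotation: %s",
                 path), call. = FALSE)
  origin <- as.numeric(aff_lps[, 4])
  if (is.null(modality)) {
    hdr <- RNifti::niftiHeader(img)
    lbl <- trimws(hdr$intent_name)
    if (!nzchar(lbl)) lbl <- trimws(hdr$descrip)
    modality <- if (lbl %in% c("CT", "MR", "DOSE", "MASK")) lbl else "CT"
  }
  data <- array(as.numeric(img), dim = dim(img))
  if (modality == "MASK")
    binary_mask(data, spacing, origin, direction)
  else
    image_volume(data, spacing, origin, direction, modality)
}

#' Write a volume to a NIfTI file
#'
#' Masks are stored as unsigned 8-bit integers, everything else as 32-bit
#' float.  Out-of-scan sentinel voxels (`NA`) are stored as NaN; they
#' round-trip through [read_volume()].
#'
#' @param vol an [image_volume()] or [binary_mask()].
#' @param path output path (`.nii` or `.nii.gz`); the parent directory must
#'   exist.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (!dir.exists(dirname(path)))
    stop(sprintf("directory does not exist: %s", dirname(path)),
         call. = FALSE)
  aff <- rbind(cbind(ras_flip %*% (vol$direction %*% diag(vol$spacing)),
                     as.numeric(ras_flip %*% vol$origin)),
               c(0, 0, 0, 1))
  datatype <- if (vol$modality == "MASK") "uint8" else "float"
  img <- RNifti::asNifti(vol$data,
                         reference = list(
                           pixdim = c(-1, vol$spacing, 1, 1, 1, 1),
                           intent_name = vol$modality),
                         datatype = datatype)
  img <- RNifti::`sform<-`(img, structure(aff, code = 1L))
  img <- RNifti::`qform<-`(img, structure(aff, code = 1L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
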