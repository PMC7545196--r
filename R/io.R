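# NIfTI volume I/O. Voxel spacing comes from the header; intensities are
# kept on the 12-bit [0, 4095] convention, rescaling other encodings.

#' Read a NIfTI volume as an ImageVolume
#'
#' Reads a 3D NIfTI file (.nii or .nii.gz), taking voxel spacing from the
#' header pixdim. Intensities above \code{intensityMax} are linearly
#' rescaled to \code{[0, intensityMax]} with a message (12-bit convention);
#' negative values are clipped to 0.
#'
#' @param path NIfTI file path.
#' @param intensityMax encoding ceiling (default 4095).
#' @return An [ImageVolume-class].
#' @export
readImageVolume <- function(path, intensityMax = 4095) {
  if (!file.exists(path)) stop("volume file not found: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("expected a 3D volume, got ", length(dim(img)), " dimensions")
  dat <- array(as.numeric(img), dim = dim(img))
  sp <- RNifti::pixdim(img)[1:3]
  dat[dat < 0] <- 0
  mx <- max(dat)
  if (mx > intensityMax) {
    message(sprintf(
      "rescaling intensities from [0, %g] to the [0, %g] convention", mx,
      intensityMax))
    dat <- dat * (intensityMax / mx)
  }
  ImageVolume(dat, spacing = sp, intensityMax = intensityMax)
}

#' Write an ImageVolume to NIfTI
#'
#' @param volume an [ImageVolume-class].
#' @param path output path (.nii or .nii.gz).
#' @return \code{path}, invisibly.
#' @export
writeImageVolume <- function(volume, path) {
  stopifnot(is(volume, "ImageVolume"))
  img <- RNifti::asNifti(volumeData(volume))
  RNifti::pixdim(img) <- voxelSpacing(volume)
  RNifti::writeNifti(img, path)
  invisible(path)
}
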