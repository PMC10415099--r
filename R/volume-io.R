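#' Load a 3-D NIfTI volume
#'
#' Reads a `.nii`/`.nii.gz` file into an [ImageVolume-class]. A 4-D file
#' whose trailing dimension is a singleton is squeezed to 3-D. NaN voxels
#' (common along brain-extraction borders of derived maps) are replaced by
#' zero with a message. When an ADC map is requested and the stored values
#' look like mm2/s (99th percentile of positive voxels below 10), they are
#' rescaled by 1e6 into the package's working units of 1e-6 mm2/s.
#'
#' @param path path to a readable NIfTI-1 file.
#' @param expected_units `"intensity"` (default) or `"adc_1e-6_mm2_per_s"`.
#' @return An [ImageVolume-class] with spacing taken from the header.
#' @examples
#' f <- tempfile(fileext = ".nii.gz")
#' saveVolume(ImageVolume(array(1, c(8, 8, 8))), f)
#' loadVolume(f)
#' @export
loadVolume <- function(path, expected_units = "intensity") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  d <- dim(a)
  if (length(d) == 4L && d[4] == 1L) {
    a <- array(a, dim = d[1:3])
    d <- d[1:3]
  }
  if (length(d) != 3L)
    stop("expected a 3-D volume, got ", length(d), " dimensions", call. = FALSE)
  spacing <- RNifti::pixdim(img)[1:3]
  nna <- sum(is.na(a))
  if (nna > 0) {
    message(sprintf("loadVolume: replaced %d NaN voxel(s) with 0 in %s",
                    nna, basename(path)))
    a[is.na(a)] <- 0
  }
  if (identical(expected_units, .ADC_UNITS)) {
    pos <- a[a > 0]
    if (length(pos) && unname(stats::quantile(pos, 0.99, type = 7)) < 10) {
      message("loadVolume: ADC values look like mm2/s; rescaling by 1e6")
      a <- a * 1e6
    }
    a[a < 0] <- 0
  }
  ImageVolume(a, spacing = spacing, units = expected_units)
}

#' Save a volume as NIfTI
#'
#' @param vol an [ImageVolume-class].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
saveVolume <- function(vol, path) {
  stopifnot(is(vol, "ImageVolume"))
  a <- imgData(vol)
  attr(a, "pixdim") <- voxelSpacing(vol)
  RNifti::writeNifti(RNifti::asNifti(a, datatype = "double"), path)
  invisible(path)
}

#' Load a binary mask from NIfTI
#'
#' Any nonzero voxel is TRUE; NaN is treated as background.
#'
#' @param path path to a NIfTI-1 mask file.
#' @return A [BinaryMask-class].
#' @export
loadMask <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  d <- dim(a)
  if (length(d) == 4L && d[4] == 1L) {
    a <- array(a, dim = d[1:3])
    d <- d[1:3]
  }
  if (length(d) != 3L)
    stop("expected a 3-D mask, got ", length(d), " dimensions", call. = FALSE)
  a[is.na(a)] <- 0
  BinaryMask(a != 0, spacing = RNifti::pixdim(img)[1:3])
}

#' Save a binary mask as NIfTI (uint8, values 0/1)
#'
#' @param mask a [BinaryMask-class].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
saveMask <- function(mask, path) {
  stopifnot(is(mask, "BinaryMask"))
  a <- array(as.integer(imgData(mask)), dim = dim(imgData(mask)))
  attr(a, "pixdim") <- voxelSpacing(mask)
  RNifti::writeNifti(RNifti::asNifti(a, datatype = "uint8"), path)
  invisible(path)
}

#' Mask volume in millilitres
#'
#' `voxel_count * prod(spacing) / 1000`: one 2 mm isotropic voxel is
#' 0.008 mL, so e.g. 125 such voxels make 1 mL.
#'
#' @param mask a [BinaryMask-class].
#' @return volume in mL.
#' @examples
#' m <- array(FALSE, c(8, 8, 8)); m[1:5, 1:5, 1:5] <- TRUE
#' maskVolumeMl(BinaryMask(m, spacing = c(2, 2, 2)))  # 1 mL
#' @export
maskVolumeMl <- function(mask) {
  stopifnot(is(mask, "BinaryMask"))
  sum(imgData(mask)) * prod(voxelSpacing(mask)) / 1000
}
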