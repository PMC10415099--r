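# The automated delineation pipeline: ratio image -> per-slice
# normalization -> Gaussian smoothing -> contralateral (mirror)
# subtraction -> intensity threshold + dilation -> ADC band gate ->
# trace-percentile cleanup.

#' Construct a SegmentationConfig
#'
#' Defaults are the published operating point of the pipeline: intensity
#' threshold 0.75 on the processed image, one dilation pass, final ADC band
#' 200--620 (1e-6 mm2/s), and removal of candidate voxels whose trace lies
#' below the 95th percentile of the parenchymal trace distribution.
#'
#' @param smoothing_fwhm_vox Gaussian FWHM in voxels (default 5).
#' @param intensity_threshold inclusive lower cut on the processed image.
#' @param dilation_iterations 6-connected dilation passes (default 1).
#' @param adc_lower,adc_upper inclusive ADC band, 1e-6 mm2/s.
#' @param trace_percentile percentile (0-100, exclusive) of the reference
#'   trace distribution used for cleanup.
#' @param percentile_population `"parenchyma"` or `"mask"`.
#' @param csf_adc_cutoff ADC above which brain voxels count as CSF.
#' @param mirror_axis left-right axis index (default 1).
#' @param slice_axis inferior-superior axis index for per-slice
#'   normalization (default 3, axial slices).
#' @return A [SegmentationConfig-class].
#' @export
SegmentationConfig <- function(smoothing_fwhm_vox = 5,
                               intensity_threshold = 0.75,
                               dilation_iterations = 1L,
                               adc_lower = 200, adc_upper = 620,
                               trace_percentile = 95,
                               percentile_population = "parenchyma",
                               csf_adc_cutoff = 2000,
                               mirror_axis = 1L, slice_axis = 3L) {
  new("SegmentationConfig",
      smoothing_fwhm_vox = smoothing_fwhm_vox,
      intensity_threshold = intensity_threshold,
      dilation_iterations = as.integer(dilation_iterations),
      adc_lower = adc_lower, adc_upper = adc_upper,
      trace_percentile = trace_percentile,
      percentile_population = percentile_population,
      csf_adc_cutoff = csf_adc_cutoff,
      mirror_axis = as.integer(mirror_axis),
      slice_axis = as.integer(slice_axis))
}

#' Trace/ADC ratio image
#'
#' Dividing the trace image by the ADC map enhances lesion contrast: acute
#' infarcts are trace-hyperintense and ADC-hypointense, so the ratio is
#' high in the lesion and low elsewhere. Voxels outside the brain, and
#' voxels with ADC <= 0, are set to 0.
#'
#' @param trace,adc [ImageVolume-class] on one grid.
#' @param brain [BinaryMask-class] brain mask (nonempty).
#' @return an intensity [ImageVolume-class].
#' @export
ratioImage <- function(trace, adc, brain) {
  .checkSameGrid(trace, adc, brain)
  if (voxelCount(brain) == 0L) stop("brain mask is empty", call. = FALSE)
  tr <- imgData(trace); ad <- imgData(adc); b <- imgData(brain)
  out <- array(0, dim = dim(tr))
  ok <- b & ad > 0
  out[ok] <- tr[ok] / ad[ok]
  ImageVolume(out, voxelSpacing(trace), .INTENSITY_UNITS)
}

#' Per-slice normalization
#'
#' Within each slice along `slice_axis`, every in-brain voxel is divided by
#' the mean of the in-brain voxel values of that slice, making values
#' comparable across subjects and brain regions. Slices with no in-brain
#' voxels or a non-positive mean are left unchanged.
#'
#' @param img an [ImageVolume-class].
#' @param brain [BinaryMask-class] on the same grid.
#' @param slice_axis axis index of the slice direction.
#' @return normalized [ImageVolume-class].
#' @export
sliceNormalize <- function(img, brain, slice_axis = 3L) {
  .checkSameGrid(img, brain)
  a <- imgData(img); b <- imgData(brain)
  margins <- slice_axis
  sums <- apply(a * b, margins, sum)
  counts <- apply(b, margins, sum)
  means <- ifelse(counts > 0, sums / counts, 0)
  mult <- ifelse(means > 0, 1 / means, 1)
  swept <- sweep(a, slice_axis, mult, "*")
  out <- a
  out[b] <- swept[b]
  ImageVolume(out, voxelSpacing(img), imgUnits(img))
}

#' Isotropic Gaussian smoothing
#'
#' Separable Gaussian filter with sigma = FWHM / 2.3548 voxels on each
#' axis and constant-zero boundary handling; the sampled kernel extends to
#' 6 sigma and is normalized to unit sum.
#'
#' @param img an [ImageVolume-class].
#' @param fwhm_vox kernel full width at half maximum in voxels (> 0).
#' @return smoothed [ImageVolume-class].
#' @export
gaussianSmooth <- function(img, fwhm_vox = 5) {
  if (fwhm_vox <= 0) stop("fwhm_vox must be positive", call. = FALSE)
  sigma <- fwhm_vox / (2 * sqrt(2 * log(2)))
  ImageVolume(.gaussianFilter3d(imgData(img), sigma),
              voxelSpacing(img), imgUnits(img))
}

#' Contralateral (mirror) subtraction
#'
#' Subtracts the left-right flipped image and clips negatives:
#' `max(0, img - flip(img))`. Mirror-symmetric structures (skull base
#' artifacts, normal anatomy, CSF) cancel; unilateral hyperintensity
#' survives on its own side. Assumes the mid-sagittal plane coincides with
#' the array mirror plane, i.e. images registered to a symmetric template.
#'
#' @param img an [ImageVolume-class].
#' @param mirror_axis index of the left-right axis.
#' @return the clipped difference [ImageVolume-class].
#' @export
mirrorSubtract <- function(img, mirror_axis = 1L) {
  a <- imgData(img)
  flipped <- switch(mirror_axis,
                    a[dim(a)[1]:1, , , drop = FALSE],
                    a[, dim(a)[2]:1, , drop = FALSE],
                    a[, , dim(a)[3]:1, drop = FALSE])
  out <- a - flipped
  out[out < 0] <- 0
  ImageVolume(out, voxelSpacing(img), imgUnits(img))
}

#' Primary candidate mask
#'
#' Thresholds the processed (mirror-subtracted) image at
#' `intensity_threshold` (inclusive), applies `dilation_iterations` passes
#' of 6-connected binary dilation, and intersects with the brain mask.
#'
#' @param processed the mirror-subtracted [ImageVolume-class].
#' @param brain [BinaryMask-class] on the same grid.
#' @param config a [SegmentationConfig-class].
#' @return the candidate [BinaryMask-class].
#' @export
primaryMask <- function(processed, brain, config = SegmentationConfig()) {
  .checkSameGrid(processed, brain)
  m <- imgData(processed) >= config@intensity_threshold
  for (i in seq_len(config@dilation_iterations)) m <- .dilate6Once(m)
  BinaryMask(m & imgData(brain), voxelSpacing(processed))
}

#' ADC band gate
#'
#' Keeps mask voxels whose ADC lies in the closed band
#' `[adc_lower, adc_upper]` (defaults 200--620 1e-6 mm2/s, the fixed band
#' used by commercial ADC-threshold delineation).
#'
#' @param mask candidate [BinaryMask-class].
#' @param adc ADC [ImageVolume-class] on the same grid.
#' @param config a [SegmentationConfig-class].
#' @return gated [BinaryMask-class].
#' @export
adcGate <- function(mask, adc, config = SegmentationConfig()) {
  .checkSameGrid(mask, adc)
  ad <- imgData(adc)
  BinaryMask(imgData(mask) & ad >= config@adc_lower & ad <= config@adc_upper,
             voxelSpacing(mask))
}

#' Trace-percentile cleanup of scattered voxels
#'
#' Computes the `trace_percentile`-th percentile (linear interpolation
#' between order statistics) of the trace image over the reference
#' population -- brain parenchyma by default, or the candidate mask itself
#' with `percentile_population = "mask"` -- and removes candidate voxels
#' whose trace is strictly below it. This discards scattered
#' trace-hypointense voxels that pass the ADC gate but are not part of the
#' hyperintense lesion.
#'
#' @param mask candidate [BinaryMask-class].
#' @param trace trace [ImageVolume-class].
#' @param brain_parenchyma parenchyma [BinaryMask-class] (nonempty).
#' @param config a [SegmentationConfig-class].
#' @return cleaned [BinaryMask-class].
#' @export
tracePercentileCleanup <- function(mask, trace, brain_parenchyma,
                                   config = SegmentationConfig()) {
  .checkSameGrid(mask, trace, brain_parenchyma)
  tr <- imgData(trace)
  pop <- if (identical(config@percentile_population, "mask"))
    tr[imgData(mask)] else tr[imgData(brain_parenchyma)]
  if (!length(pop)) {
    if (identical(config@percentile_population, "mask")) return(mask)
    stop("parenchyma mask is empty", call. = FALSE)
  }
  cutoff <- unname(stats::quantile(pop, config@trace_percentile / 100,
                                   type = 7))
  BinaryMask(imgData(mask) & tr >= cutoff, voxelSpacing(mask))
}

#' Parenchyma mask from an ADC-based CSF exclusion rule
#'
#' Brain voxels with ADC below `csf_adc_cutoff` (default 2000 1e-6 mm2/s);
#' free-water diffusivity is ~3000, parenchyma well below 2000, so a
#' cutoff anywhere between separates the compartments.
#'
#' @param adc ADC [ImageVolume-class].
#' @param brain [BinaryMask-class].
#' @param config a [SegmentationConfig-class].
#' @return parenchyma [BinaryMask-class]; empty result raises a warning.
#' @export
parenchymaMask <- function(adc, brain, config = SegmentationConfig()) {
  .checkSameGrid(adc, brain)
  m <- imgData(brain) & imgData(adc) < config@csf_adc_cutoff
  if (!any(m)) warning("parenchyma mask is empty (csf_adc_cutoff too low?)")
  BinaryMask(m, voxelSpacing(adc))
}

#' Automated lesion delineation
#'
#' Runs the full pipeline on co-registered, brain-extracted b0/trace/ADC
#' volumes: trace/ADC ratio, per-slice normalization, isotropic Gaussian
#' smoothing, contralateral subtraction, inclusive intensity threshold
#' with dilation (the primary mask), ADC band gating, and trace-percentile
#' cleanup. Surviving voxel counts are recorded per stage. The final mask
#' may be empty -- very small or high-ADC lesions can fail every gate.
#'
#' @param b0,trace,adc [ImageVolume-class] volumes on one grid (b0 is
#'   accepted for interface completeness; the pipeline itself uses trace
#'   and ADC).
#' @param brain [BinaryMask-class] brain mask.
#' @param config a [SegmentationConfig-class].
#' @return A [SegmentationResult-class].
#' @examples
#' case <- generateCase(PhantomSpec(seed = 7,
#'                                  lesion_radii_vox = c(6.5, 6.5, 6.5)))
#' res <- delineate(case@b0, case@trace, case@adc, case@brain_mask)
#' diceCoefficient(res@lesion_mask, case@truth_lesion)
#' @export
delineate <- function(b0, trace, adc, brain, config = SegmentationConfig()) {
  .checkSameGrid(b0, trace, adc, brain)
  ratio <- ratioImage(trace, adc, brain)
  norm <- sliceNormalize(ratio, brain, config@slice_axis)
  smooth <- gaussianSmooth(norm, config@smoothing_fwhm_vox)
  processed <- mirrorSubtract(smooth, config@mirror_axis)
  thresholded <- imgData(processed) >= config@intensity_threshold
  primary <- primaryMask(processed, brain, config)
  parenchyma <- parenchymaMask(adc, brain, config)
  gated <- adcGate(primary, adc, config)
  lesion <- tracePercentileCleanup(gated, trace, parenchyma, config)
  stage_log <- c(threshold = sum(thresholded),
                 primary_mask = voxelCount(primary),
                 adc_gate = voxelCount(gated),
                 trace_cleanup = voxelCount(lesion))
  new("SegmentationResult", lesion_mask = lesion, primary_mask = primary,
      processed_image = processed, stage_log = stage_log, config = config)
}
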