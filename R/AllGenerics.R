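#' Voxel data of a volume or mask
#' @param x an [ImageVolume-class] or [BinaryMask-class].
#' @return the underlying 3-D array (numeric for volumes, logical for masks).
#' @export
setGeneric("imgData", function(x) standardGeneric("imgData"))

#' Voxel spacing in mm
#' @param x an [ImageVolume-class] or [BinaryMask-class].
#' @return numeric(3) voxel edge lengths in mm.
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' Units tag of a volume
#' @param x an [ImageVolume-class].
#' @return `"intensity"` or `"adc_1e-6_mm2_per_s"`.
#' @export
setGeneric("imgUnits", function(x) standardGeneric("imgUnits"))

#' Number of TRUE voxels in a mask
#' @param x a [BinaryMask-class].
#' @return integer voxel count.
#' @export
setGeneric("voxelCount", function(x) standardGeneric("voxelCount"))

#' @rdname imgData
setMethod("imgData", "ImageVolume", function(x) x@data)
#' @rdname imgData
setMethod("imgData", "BinaryMask", function(x) x@data)
#' @rdname voxelSpacing
setMethod("voxelSpacing", "ImageVolume", function(x) x@spacing)
#' @rdname voxelSpacing
setMethod("voxelSpacing", "BinaryMask", function(x) x@spacing)
#' @rdname imgUnits
setMethod("imgUnits", "ImageVolume", function(x) x@units)
#' @rdname voxelCount
setMethod("voxelCount", "BinaryMask", function(x) sum(x@data))

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("ImageVolume %dx%dx%d, spacing %s mm, units '%s'\n",
              d[1], d[2], d[3],
              paste(format(object@spacing), collapse = "x"), object@units))
  cat(sprintf("  range [%g, %g]\n", min(object@data), max(object@data)))
})

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@data)
  cat(sprintf("BinaryMask %dx%dx%d, spacing %s mm: %d voxels (%.3f mL)\n",
              d[1], d[2], d[3],
              paste(format(object@spacing), collapse = "x"),
              sum(object@data), maskVolumeMl(object)))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec %s @ %s mm, b=%g s/mm2, seed %d\n",
              paste(object@grid_shape, collapse = "x"),
              paste(format(object@spacing_mm), collapse = "x"),
              object@b_value, object@seed))
  cat(sprintf("  ADC (1e-6 mm2/s): lesion %g+/-%g, parenchyma %g+/-%g, CSF %g\n",
              object@lesion_adc_mean, object@lesion_adc_sd,
              object@parenchyma_adc_mean, object@parenchyma_adc_sd,
              object@csf_adc_mean))
  cat(sprintf("  s0 %g, noise sd %g, lesion radii (vox) %s\n",
              object@s0_mean, object@noise_sd,
              paste(format(object@lesion_radii_vox), collapse = ", ")))
})

setMethod("show", "PhantomCase", function(object) {
  cat("PhantomCase\n  ")
  show(object@truth_lesion)
  cat(sprintf("  brain: %d voxels\n", voxelCount(object@brain_mask)))
})

setMethod("show", "SegmentationConfig", function(object) {
  cat("SegmentationConfig\n")
  cat(sprintf("  smoothing FWHM %g vox | intensity >= %g | dilation x%d\n",
              object@smoothing_fwhm_vox, object@intensity_threshold,
              object@dilation_iterations))
  cat(sprintf("  ADC band [%g, %g] 1e-6 mm2/s | trace percentile %g (%s) | CSF cutoff %g\n",
              object@adc_lower, object@adc_upper, object@trace_percentile,
              object@percentile_population, object@csf_adc_cutoff))
})

setMethod("show", "SegmentationResult", function(object) {
  cat("SegmentationResult\n  lesion: ")
  show(object@lesion_mask)
  cat("  stage log (surviving voxels):\n")
  for (nm in names(object@stage_log))
    cat(sprintf("    %-18s %d\n", nm, as.integer(object@stage_log[[nm]])))
})

setMethod("show", "ROCResult", function(object) {
  cat(sprintf("ROCResult: %d thresholds, %g positive / %g negative voxels\n",
              length(object@thresholds), object@n_pos, object@n_neg))
  i <- match(object@optimal_threshold, object@thresholds)
  cat(sprintf("  optimal ADC <= %g: J = %.3f (sens %.3f, spec %.3f), AUC = %.3f\n",
              object@optimal_threshold, object@optimal_youden,
              object@sensitivity[i], object@specificity[i], object@auc))
})

setMethod("show", "AgreementStats", function(object) {
  cat(sprintf("AgreementStats (n = %d)\n", object@n))
  cat(sprintf("  bias %.3f mL, limits of agreement [%.3f, %.3f]\n",
              object@bias, object@loa_low, object@loa_high))
  cat(sprintf("  Pearson r = %.3f; fit on reference: slope %.3f, intercept %.3f, adj R2 %.3f\n",
              object@pearson_r, object@slope, object@intercept, object@adj_r2))
})

setMethod("show", "RegressionReport", function(object) {
  cat(sprintf("RegressionReport: response '%s', n = %d (%d dropped), adj R2 = %.3f\n",
              object@response_name, object@n, object@n_dropped, object@adj_r2))
  print(object@coefficients, row.names = FALSE, digits = 3)
})
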