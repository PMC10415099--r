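#' @import methods
NULL

.ADC_UNITS <- "adc_1e-6_mm2_per_s"
.INTENSITY_UNITS <- "intensity"

#' ImageVolume: a 3-D scalar image on a regular voxel grid
#'
#' The basic container for the b0, trace (b = 1000 s/mm\eqn{^2}) and ADC map
#' volumes. Intensities are in arbitrary units for b0/trace; ADC maps carry
#' the units tag `"adc_1e-6_mm2_per_s"` and must be finite and non-negative.
#'
#' @slot data numeric 3-D array of voxel values.
#' @slot spacing numeric(3), voxel edge lengths in mm (all > 0).
#' @slot units one of `"intensity"` or `"adc_1e-6_mm2_per_s"`.
#' @export
setClass("ImageVolume",
  representation(data = "array", spacing = "numeric", units = "character"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@data)) != 3L)
      msg <- c(msg, "data must be a 3-D array")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 positive finite values (mm)")
    if (length(object@units) != 1L ||
        !object@units %in% c(.INTENSITY_UNITS, .ADC_UNITS))
      msg <- c(msg, sprintf("units must be one of '%s', '%s'",
                            .INTENSITY_UNITS, .ADC_UNITS))
    if (anyNA(object@data))
      msg <- c(msg, "data must not contain NA/NaN")
    if (length(object@units) == 1L && identical(object@units, .ADC_UNITS)) {
      if (any(!is.finite(object@data)) || any(object@data < 0))
        msg <- c(msg, "an ADC volume must be finite and non-negative")
    }
    if (length(msg)) msg else TRUE
  })

#' BinaryMask: a 3-D boolean lattice on the same grid as its volumes
#'
#' Holds brain, parenchyma, candidate, lesion and reference masks. Any
#' operation combining a mask with a volume checks that grid shape and
#' spacing agree exactly.
#'
#' @slot data logical 3-D array.
#' @slot spacing numeric(3), voxel edge lengths in mm (all > 0).
#' @export
setClass("BinaryMask",
  representation(data = "array", spacing = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@data)) != 3L || !is.logical(object@data))
      msg <- c(msg, "data must be a logical 3-D array")
    if (anyNA(object@data))
      msg <- c(msg, "mask must not contain NA")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 positive finite values (mm)")
    if (length(msg)) msg else TRUE
  })

#' Construct an ImageVolume
#'
#' @param data numeric 3-D array (NaN/NA are replaced by 0 with a message,
#'   mirroring the treatment of brain-extraction border voxels in derived
#'   maps).
#' @param spacing numeric(3) voxel edge lengths in mm.
#' @param units `"intensity"` (default) or `"adc_1e-6_mm2_per_s"`.
#' @return An [ImageVolume-class] object.
#' @export
ImageVolume <- function(data, spacing = c(2, 2, 2), units = .INTENSITY_UNITS) {
  data <- array(as.double(data), dim = dim(as.array(data)))
  nna <- sum(is.na(data))
  if (nna > 0) {
    message(sprintf("ImageVolume: replaced %d NaN/NA voxel(s) with 0", nna))
    data[is.na(data)] <- 0
  }
  new("ImageVolume", data = data, spacing = as.numeric(spacing),
      units = units)
}

#' Construct a BinaryMask
#'
#' @param data logical (or coercible 0/1) 3-D array.
#' @param spacing numeric(3) voxel edge lengths in mm.
#' @return A [BinaryMask-class] object.
#' @export
BinaryMask <- function(data, spacing = c(2, 2, 2)) {
  d <- dim(as.array(data))
  data <- if (is.logical(data)) array(as.logical(data), dim = d)
          else array(as.vector(data) != 0, dim = d)
  new("BinaryMask", data = data, spacing = as.numeric(spacing))
}

#' PhantomSpec: parameters of one synthetic DWI case
#'
#' Describes the geometry, diffusion parameters and noise of a synthetic
#' brain: an ellipsoidal, mirror-symmetric brain with symmetric CSF
#' (ventricle-like) blobs and a single ellipsoidal ischemic lesion whose ADC
#' sits below the parenchymal ADC. The trace signal follows the
#' mono-exponential decay law S = S0 exp(-b ADC).
#'
#' @slot grid_shape integer(3) grid size in voxels; the first axis is
#'   left-right and must be even so the mid-sagittal mirror plane falls
#'   exactly between the two central voxel columns.
#' @slot spacing_mm numeric(3) voxel size in mm (default 2 mm isotropic).
#' @slot s0_mean baseline (b = 0) signal intensity inside the brain.
#' @slot parenchyma_adc_mean,parenchyma_adc_sd parenchymal ADC distribution
#'   in 1e-6 mm2/s.
#' @slot lesion_adc_mean,lesion_adc_sd lesion ADC distribution in
#'   1e-6 mm2/s; the mean must be below the parenchymal mean.
#' @slot csf_adc_mean CSF ADC mean in 1e-6 mm2/s; must exceed the
#'   parenchymal mean.
#' @slot lesion_center_vox numeric(3) lesion ellipsoid centre (voxel
#'   coordinates, 1-based).
#' @slot lesion_radii_vox numeric(3) lesion ellipsoid semi-axes in voxels.
#' @slot b_value diffusion weighting in s/mm2 (default 1000).
#' @slot noise_sd additive Gaussian noise sd applied to b0 and trace.
#' @slot seed integer RNG seed; identical spec + seed gives bit-identical
#'   output.
#' @export
setClass("PhantomSpec",
  representation(grid_shape = "integer", spacing_mm = "numeric",
                 s0_mean = "numeric",
                 parenchyma_adc_mean = "numeric", parenchyma_adc_sd = "numeric",
                 lesion_adc_mean = "numeric", lesion_adc_sd = "numeric",
                 csf_adc_mean = "numeric",
                 lesion_center_vox = "numeric", lesion_radii_vox = "numeric",
                 b_value = "numeric", noise_sd = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@grid_shape) != 3L || any(object@grid_shape < 8L))
      msg <- c(msg, "grid_shape must be 3 integers >= 8")
    if (length(object@grid_shape) == 3L && object@grid_shape[1] %% 2L != 0L)
      msg <- c(msg, "first grid axis must be even (mirror plane between the two central columns)")
    if (any(object@spacing_mm <= 0)) msg <- c(msg, "spacing_mm must be positive")
    if (!(object@lesion_adc_mean < object@parenchyma_adc_mean &&
          object@parenchyma_adc_mean < object@csf_adc_mean))
      msg <- c(msg, "need lesion_adc_mean < parenchyma_adc_mean < csf_adc_mean")
    if (object@s0_mean <= 0) msg <- c(msg, "s0_mean must be positive")
    if (object@b_value <= 0) msg <- c(msg, "b_value must be positive")
    if (object@noise_sd < 0) msg <- c(msg, "noise_sd must be >= 0")
    if (any(object@lesion_radii_vox <= 0))
      msg <- c(msg, "lesion_radii_vox must be positive")
    if (length(msg)) msg else TRUE
  })

#' PhantomCase: one synthetic subject
#'
#' @slot b0,trace,adc [ImageVolume-class] volumes on one grid.
#' @slot brain_mask,truth_lesion [BinaryMask-class]; the truth lesion is
#'   exactly the set of lesion-compartment voxels and is contained in the
#'   brain mask.
#' @slot spec the generating [PhantomSpec-class].
#' @export
setClass("PhantomCase",
  representation(b0 = "ImageVolume", trace = "ImageVolume",
                 adc = "ImageVolume", brain_mask = "BinaryMask",
                 truth_lesion = "BinaryMask", spec = "PhantomSpec"))

#' SegmentationConfig: tunables of the delineation pipeline
#'
#' Every knob of the thresholding pipeline: ratio-image \eqn{\to} slice
#' normalization \eqn{\to} Gaussian smoothing \eqn{\to} contralateral
#' (mirror) subtraction \eqn{\to} intensity threshold \eqn{\to} dilation
#' \eqn{\to} ADC band gate \eqn{\to} trace-percentile cleanup.
#'
#' @slot smoothing_fwhm_vox full width at half maximum of the isotropic
#'   Gaussian smoothing kernel, in voxels (default 5).
#' @slot intensity_threshold lower cut applied to the processed
#'   (mirror-subtracted) image; comparison is inclusive (default 0.75).
#' @slot dilation_iterations iterations of 6-connected binary dilation of
#'   the thresholded mask, restricted to the brain (default 1).
#' @slot adc_lower,adc_upper inclusive ADC band in 1e-6 mm2/s that final
#'   lesion voxels must satisfy (defaults 200 and 620).
#' @slot trace_percentile percentile of the reference trace distribution
#'   below which candidate voxels are discarded as scattered artifacts
#'   (default 95).
#' @slot percentile_population `"parenchyma"` (default) or `"mask"`: the
#'   population over which the trace percentile is computed.
#' @slot csf_adc_cutoff ADC (1e-6 mm2/s) above which brain voxels are
#'   treated as CSF when building the parenchyma mask (default 2000).
#' @slot mirror_axis index of the left-right axis used for contralateral
#'   subtraction (default 1).
#' @slot slice_axis index of the inferior-superior axis; normalization is
#'   performed per axial slice along it (default 3).
#' @export
setClass("SegmentationConfig",
  representation(smoothing_fwhm_vox = "numeric", intensity_threshold = "numeric",
                 dilation_iterations = "integer",
                 adc_lower = "numeric", adc_upper = "numeric",
                 trace_percentile = "numeric", percentile_population = "character",
                 csf_adc_cutoff = "numeric",
                 mirror_axis = "integer", slice_axis = "integer"),
  validity = function(object) {
    msg <- character()
    if (!(object@adc_lower >= 0 && object@adc_lower < object@adc_upper))
      msg <- c(msg, "need 0 <= adc_lower < adc_upper")
    if (!(object@trace_percentile >= 0 && object@trace_percentile < 100))
      msg <- c(msg, "trace_percentile must lie in [0, 100)")
    if (object@dilation_iterations < 0L)
      msg <- c(msg, "dilation_iterations must be >= 0")
    if (object@smoothing_fwhm_vox <= 0)
      msg <- c(msg, "smoothing_fwhm_vox must be positive")
    if (!object@mirror_axis %in% 1:3 || !object@slice_axis %in% 1:3)
      msg <- c(msg, "mirror_axis and slice_axis must be 1, 2 or 3")
    if (!object@percentile_population %in% c("parenchyma", "mask"))
      msg <- c(msg, "percentile_population must be 'parenchyma' or 'mask'")
    if (length(msg)) msg else TRUE
  })

#' SegmentationResult: output of [delineate()]
#'
#' @slot lesion_mask final automated lesion [BinaryMask-class] (possibly
#'   empty).
#' @slot primary_mask candidate mask before ADC gating.
#' @slot processed_image the mirror-subtracted [ImageVolume-class] the
#'   intensity threshold was applied to.
#' @slot stage_log named numeric vector of surviving voxel counts per
#'   pipeline stage.
#' @slot config the [SegmentationConfig-class] used.
#' @export
setClass("SegmentationResult",
  representation(lesion_mask = "BinaryMask", primary_mask = "BinaryMask",
                 processed_image = "ImageVolume", stage_log = "numeric",
                 config = "SegmentationConfig"))

#' ROCResult: a voxelwise ADC threshold sweep
#'
#' The classifier is "ADC \eqn{\le} t is infarct". Sensitivity is therefore
#' non-decreasing and specificity non-increasing in t.
#'
#' @slot thresholds ascending ADC thresholds in 1e-6 mm2/s.
#' @slot sensitivity,specificity,youden per-threshold rates;
#'   J = sensitivity + specificity - 1.
#' @slot counts per-threshold integer matrix with columns TP, FP, FN, TN.
#' @slot optimal_threshold argmax-Youden threshold (ties broken toward the
#'   lowest threshold).
#' @slot optimal_youden the Youden index at the optimum.
#' @slot auc trapezoidal area under the ROC curve with (0,0) and (1,1)
#'   appended.
#' @slot n_pos,n_neg voxel counts of the positive (truth) and negative
#'   (search region minus truth) classes.
#' @export
setClass("ROCResult",
  representation(thresholds = "numeric", sensitivity = "numeric",
                 specificity = "numeric", youden = "numeric",
                 counts = "matrix", optimal_threshold = "numeric",
                 optimal_youden = "numeric", auc = "numeric",
                 n_pos = "numeric", n_neg = "numeric"),
  validity = function(object) {
    msg <- character()
    if (is.unsorted(object@thresholds))
      msg <- c(msg, "thresholds must be ascending")
    k <- length(object@thresholds)
    if (length(object@sensitivity) != k || length(object@specificity) != k ||
        length(object@youden) != k)
      msg <- c(msg, "rate vectors must match the threshold grid")
    if (max(abs(object@youden -
                (object@sensitivity + object@specificity - 1))) > 1e-12)
      msg <- c(msg, "youden must equal sensitivity + specificity - 1")
    if (object@auc < 0 || object@auc > 1)
      msg <- c(msg, "auc must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  })

#' AgreementStats: Bland-Altman and correlation summary of paired volumes
#'
#' @slot bias mean difference a - b in mL.
#' @slot loa_low,loa_high limits of agreement, bias -/+ 1.96 sd of the
#'   differences (sample sd, n - 1 denominator).
#' @slot pearson_r Pearson correlation of the two volume lists.
#' @slot slope,intercept,adj_r2 least-squares fit of a on b (b is the
#'   reference method).
#' @slot n number of pairs.
#' @export
setClass("AgreementStats",
  representation(bias = "numeric", loa_low = "numeric", loa_high = "numeric",
                 pearson_r = "numeric", slope = "numeric",
                 intercept = "numeric", adj_r2 = "numeric", n = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!(object@loa_low <= object@bias && object@bias <= object@loa_high))
      msg <- c(msg, "limits of agreement must bracket the bias")
    if (abs(object@pearson_r) > 1 + 1e-12)
      msg <- c(msg, "|pearson_r| must be <= 1")
    if (length(msg)) msg else TRUE
  })

#' RegressionReport: standardized-coefficient linear regression
#'
#' Response and predictors are z-scored before ordinary least squares, so
#' the coefficients are standardized betas directly comparable in size.
#'
#' @slot response_name label of the response (e.g. "dice" or "youden").
#' @slot coefficients data.frame with columns predictor, beta, ci_low,
#'   ci_high, p_value (95% Wald intervals, two-sided t tests).
#' @slot adj_r2 adjusted R-squared of the fit.
#' @slot n subjects used after dropping incomplete cases.
#' @slot n_dropped incomplete cases removed before fitting.
#' @export
setClass("RegressionReport",
  representation(response_name = "character", coefficients = "data.frame",
                 adj_r2 = "numeric", n = "numeric", n_dropped = "numeric"))
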