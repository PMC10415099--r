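# Voxelwise ROC analysis for ADC threshold discovery. The classifier is
# "ADC <= t is infarct"; the negative class is the search region minus the
# truth lesion (whole-brain parenchyma by default, or a lesion-centred
# dilated region).

.rocFromCounts <- function(thresholds, TP, FP, FN, TN) {
  n_pos <- TP[1] + FN[1]
  n_neg <- FP[1] + TN[1]
  sens <- TP / n_pos
  spec <- TN / n_neg
  youden <- sens + spec - 1
  opt <- which.max(youden)          # first max = lowest threshold on ties
  x <- c(0, 1 - spec, 1)
  y <- c(0, sens, 1)
  auc <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  new("ROCResult", thresholds = as.numeric(thresholds),
      sensitivity = sens, specificity = spec, youden = youden,
      counts = cbind(TP = TP, FP = FP, FN = FN, TN = TN),
      optimal_threshold = as.numeric(thresholds[opt]),
      optimal_youden = youden[opt], auc = auc,
      n_pos = n_pos, n_neg = n_neg)
}

#' Voxelwise ROC sweep over ADC thresholds
#'
#' For each threshold t, voxels of the search region with ADC <= t are
#' classified infarct; TP/FP/FN/TN are counted against the truth mask
#' within the region. The optimal threshold maximises the Youden index
#' J = sensitivity + specificity - 1 (ties broken toward the lowest
#' threshold) and the AUC is the trapezoidal area under the ROC curve
#' with endpoints (0,0) and (1,1) appended.
#'
#' @param adc ADC [ImageVolume-class], 1e-6 mm2/s.
#' @param truth nonempty reference lesion [BinaryMask-class], contained in
#'   `search_region`.
#' @param search_region nonempty [BinaryMask-class] (e.g. whole-brain
#'   parenchyma, or a dilated lesion neighbourhood).
#' @param thresholds ascending threshold grid; the default integer grid
#'   0..1500 covers the full parenchymal ADC range at the 1e-6 mm2/s
#'   resolution thresholds are conventionally reported in.
#' @return An [ROCResult-class].
#' @examples
#' case <- generateCase(PhantomSpec(seed = 3))
#' par <- parenchymaMask(case@adc, case@brain_mask)
#' rocSweep(case@adc, case@truth_lesion, par)
#' @export
rocSweep <- function(adc, truth, search_region, thresholds = 0:1500) {
  .checkSameGrid(adc, truth, search_region)
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly ascending", call. = FALSE)
  tm <- imgData(truth); sm <- imgData(search_region)
  if (!any(tm)) stop("truth mask is empty: ROC undefined", call. = FALSE)
  if (!any(sm)) stop("search region is empty", call. = FALSE)
  if (any(tm & !sm))
    stop("truth mask must be contained in the search region", call. = FALSE)
  ad <- imgData(adc)
  vt <- sort(ad[tm])
  vb <- sort(ad[sm & !tm])
  if (!length(vb)) stop("search region contains no negative voxels",
                        call. = FALSE)
  TP <- findInterval(thresholds, vt)
  FP <- findInterval(thresholds, vb)
  .rocFromCounts(thresholds, TP, FP, length(vt) - TP, length(vb) - FP)
}

#' Lesion-centred search region by dilation
#'
#' Dilates the truth lesion by `iterations` 6-connected steps and
#' intersects with the parenchyma, narrowing the ROC comparator from the
#' whole brain to the lesion's vicinity. The fraction of parenchyma
#' excluded is attached as attribute `"excluded_fraction"`.
#'
#' @param truth nonempty lesion [BinaryMask-class].
#' @param brain_parenchyma parenchyma [BinaryMask-class].
#' @param iterations dilation steps (default 3, which excludes roughly 96%
#'   of the parenchyma for mid-sized phantom lesions).
#' @return the search-region [BinaryMask-class].
#' @export
dilatedSearchRegion <- function(truth, brain_parenchyma, iterations = 3L) {
  .checkSameGrid(truth, brain_parenchyma)
  tm <- imgData(truth)
  if (!any(tm)) stop("truth mask is empty", call. = FALSE)
  m <- tm
  for (i in seq_len(iterations)) m <- .dilate6Once(m)
  region <- BinaryMask(m & imgData(brain_parenchyma), voxelSpacing(truth))
  np <- voxelCount(brain_parenchyma)
  attr(region, "excluded_fraction") <-
    if (np > 0) 1 - voxelCount(region) / np else NA_real_
  region
}

#' Pool per-subject ROC count tables
#'
#' Sums TP/FP/FN/TN across subjects at every threshold of a shared grid,
#' then recomputes rates, Youden index, the optimal threshold and AUC.
#' Pooling answers "what single generalized threshold works best across
#' the cohort", which can be (and typically is) worse than each subject's
#' own optimum.
#'
#' @param results list of [ROCResult-class] objects, or of per-subject
#'   count tables (data.frames with columns `threshold`, `TP`, `FP`, `FN`,
#'   `TN`), all evaluated on identical threshold grids.
#' @return pooled [ROCResult-class].
#' @export
pooledRoc <- function(results) {
  if (!length(results)) stop("no ROC results to pool", call. = FALSE)
  grids <- lapply(results, function(r)
    if (is(r, "ROCResult")) r@thresholds else as.numeric(r$threshold))
  for (g in grids[-1]) if (!isTRUE(all.equal(g, grids[[1]])))
    stop("all subjects must share one threshold grid", call. = FALSE)
  tabs <- lapply(results, function(r)
    if (is(r, "ROCResult")) r@counts
    else cbind(TP = r$TP, FP = r$FP, FN = r$FN, TN = r$TN))
  counts <- Reduce(`+`, tabs)
  .rocFromCounts(grids[[1]], counts[, "TP"], counts[, "FP"],
                 counts[, "FN"], counts[, "TN"])
}

#' Per-threshold count table of an ROC sweep
#'
#' @param roc an [ROCResult-class].
#' @return data.frame with threshold, TP, FP, FN, TN, sensitivity,
#'   specificity and Youden index per threshold.
#' @export
rocCountTable <- function(roc) {
  stopifnot(is(roc, "ROCResult"))
  data.frame(threshold = roc@thresholds,
             TP = roc@counts[, "TP"], FP = roc@counts[, "FP"],
             FN = roc@counts[, "FN"], TN = roc@counts[, "TN"],
             sensitivity = roc@sensitivity, specificity = roc@specificity,
             youden = roc@youden)
}
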