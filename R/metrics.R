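# Agreement and performance statistics: Dice overlap, lesion summaries,
# Bland-Altman limits of agreement, and standardized-coefficient linear
# regression of performance on patient factors.

#' Dice overlap coefficient
#'
#' `2 TP / (2 TP + FP + FN)` between two binary masks on one grid. If both
#' masks are empty the coefficient is defined as 1 (perfect agreement on
#' absence) with a warning.
#'
#' @param pred,truth [BinaryMask-class] objects on the same grid.
#' @return Dice coefficient in \[0, 1\].
#' @examples
#' a <- array(FALSE, c(4, 4, 4)); b <- a
#' a[1:2, 1, 1] <- TRUE; b[1:4, 1, 1] <- TRUE
#' diceCoefficient(BinaryMask(a), BinaryMask(b))  # 2*2/(2*2+0+2) = 0.667
#' @export
diceCoefficient <- function(pred, truth) {
  .checkSameGrid(pred, truth)
  p <- imgData(pred); t <- imgData(truth)
  tp <- sum(p & t)
  fp <- sum(p & !t)
  fn <- sum(!p & t)
  if (tp + fp + fn == 0) {
    warning("both masks empty: Dice defined as 1")
    return(1)
  }
  2 * tp / (2 * tp + fp + fn)
}

#' Volume and ADC summary of a lesion mask
#'
#' @param mask lesion [BinaryMask-class].
#' @param adc ADC [ImageVolume-class] on the same grid.
#' @return list with `volume_ml`, `mean_adc`, `median_adc`; an empty mask
#'   yields volume 0 and NA summaries with a warning.
#' @export
lesionSummary <- function(mask, adc) {
  .checkSameGrid(mask, adc)
  vals <- imgData(adc)[imgData(mask)]
  if (!length(vals)) {
    warning("empty mask: ADC summaries undefined")
    return(list(volume_ml = 0, mean_adc = NA_real_, median_adc = NA_real_))
  }
  list(volume_ml = maskVolumeMl(mask),
       mean_adc = mean(vals),
       median_adc = stats::median(vals))
}

#' Bland-Altman volumetric agreement
#'
#' Differences are oriented `a - b` (pass the manual/reference volumes as
#' `a`). Bias is the mean difference; limits of agreement are
#' bias +/- 1.96 sample sd (n - 1 denominator). Also reports the Pearson
#' correlation and the least-squares fit of `a` on `b` (treating `b` as
#' the reference method on the x-axis).
#'
#' @param volumes_a,volumes_b paired volume lists in mL, equal length >= 2
#'   (two pairs are the minimum for a sample sd; meaningful limits need
#'   more).
#' @return An [AgreementStats-class].
#' @export
blandAltman <- function(volumes_a, volumes_b) {
  a <- as.numeric(volumes_a); b <- as.numeric(volumes_b)
  if (length(a) != length(b)) stop("volume lists differ in length",
                                   call. = FALSE)
  if (length(a) < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- a - b
  bias <- mean(d)
  s <- stats::sd(d)
  r <- if (stats::sd(a) > 0 && stats::sd(b) > 0) stats::cor(a, b) else 1
  fit <- stats::lm(a ~ b)
  new("AgreementStats", bias = bias,
      loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
      pearson_r = r,
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      adj_r2 = summary(fit)$adj.r.squared,
      n = length(a))
}

#' Linear regression with standardized coefficients
#'
#' z-scores the response and every predictor, then fits ordinary least
#' squares, so coefficients are standardized betas with 95% Wald
#' confidence intervals and two-sided t-test p-values (no multiplicity
#' correction). Cases with missing values are dropped and counted.
#'
#' @param response numeric response (e.g. per-subject Dice or Youden).
#' @param predictors data.frame (or named list) of numeric predictors.
#' @param response_name label stored in the report.
#' @return A [RegressionReport-class].
#' @examples
#' x <- rnorm(50)
#' standardizedRegression(2 * x, data.frame(x = x))
#' @export
standardizedRegression <- function(response, predictors,
                                   response_name = "response") {
  predictors <- as.data.frame(predictors)
  y <- as.numeric(response)
  if (nrow(predictors) != length(y))
    stop("response and predictors differ in length", call. = FALSE)
  complete <- stats::complete.cases(predictors) & !is.na(y)
  n_dropped <- sum(!complete)
  y <- y[complete]
  X <- predictors[complete, , drop = FALSE]
  p <- ncol(X)
  if (length(y) <= p + 1)
    stop("need more observations than predictors + 1", call. = FALSE)
  sds <- vapply(X, stats::sd, numeric(1))
  if (any(sds == 0))
    stop("constant predictor(s): ", paste(names(X)[sds == 0], collapse = ", "),
         call. = FALSE)
  if (stats::sd(y) == 0) stop("constant response", call. = FALSE)
  Z <- as.data.frame(lapply(X, function(v) (v - mean(v)) / stats::sd(v)))
  if (p > 1) {
    cn <- kappa(crossprod(as.matrix(Z)) / (length(y) - 1), exact = TRUE)
    if (cn > 1e8) {
      cm <- abs(stats::cor(as.matrix(Z))); diag(cm) <- 0
      worst <- which(cm == max(cm), arr.ind = TRUE)[1, ]
      stop(sprintf("collinear predictors: '%s' and '%s'",
                   names(X)[worst[1]], names(X)[worst[2]]), call. = FALSE)
    }
  }
  Z$.y <- (y - mean(y)) / stats::sd(y)
  fit <- stats::lm(.y ~ ., data = Z)
  sm <- summary(fit)
  ci <- stats::confint(fit, level = 0.95)
  keep <- rownames(sm$coefficients) != "(Intercept)"
  coefs <- data.frame(
    predictor = rownames(sm$coefficients)[keep],
    beta = unname(sm$coefficients[keep, "Estimate"]),
    ci_low = unname(ci[keep, 1]),
    ci_high = unname(ci[keep, 2]),
    p_value = unname(sm$coefficients[keep, "Pr(>|t|)"]),
    stringsAsFactors = FALSE)
  new("RegressionReport", response_name = response_name,
      coefficients = coefs, adj_r2 = sm$adj.r.squared,
      n = length(y), n_dropped = n_dropped)
}
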