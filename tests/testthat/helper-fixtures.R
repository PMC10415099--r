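# Small builders shared across test files.

tinyVolume <- function(values, dim = c(4, 4, 4), spacing = c(2, 2, 2),
                       units = "intensity") {
  ImageVolume(array(values, dim = dim), spacing = spacing, units = units)
}

tinyMask <- function(idx, dim = c(4, 4, 4), spacing = c(2, 2, 2)) {
  m <- array(FALSE, dim = dim)
  m[idx] <- TRUE
  BinaryMask(m, spacing = spacing)
}

fullMask <- function(dim = c(4, 4, 4), spacing = c(2, 2, 2)) {
  BinaryMask(array(TRUE, dim = dim), spacing = spacing)
}

# Exhaustive voxel-by-voxel Dice, the oracle for diceCoefficient().
bruteDice <- function(pred, truth) {
  p <- imgData(pred); t <- imgData(truth)
  tp <- 0L; fp <- 0L; fn <- 0L
  for (i in seq_along(p)) {
    if (p[i] && t[i]) tp <- tp + 1L
    else if (p[i]) fp <- fp + 1L
    else if (t[i]) fn <- fn + 1L
  }
  if (tp + fp + fn == 0L) return(1)
  2 * tp / (2 * tp + fp + fn)
}

# Exhaustive per-voxel classification at one threshold, the oracle for
# rocSweep() counts.
bruteRocCounts <- function(adc, truth, region, t) {
  a <- imgData(adc); tm <- imgData(truth); rm_ <- imgData(region)
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(a)) {
    if (!rm_[i]) next
    pos <- a[i] <= t
    if (pos && tm[i]) tp <- tp + 1L
    else if (pos) fp <- fp + 1L
    else if (tm[i]) fn <- fn + 1L
    else tn <- tn + 1L
  }
  c(TP = tp, FP = fp, FN = fn, TN = tn)
}
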