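# Internal array helpers shared by the segmentation and ROC modules.

# Error unless all objects (volumes/masks) share grid shape and spacing.
.checkSameGrid <- function(...) {
  objs <- list(...)
  ref <- objs[[1]]
  rd <- dim(imgData(ref)); rs <- voxelSpacing(ref)
  for (o in objs[-1]) {
    if (!identical(dim(imgData(o)), rd))
      stop("grid mismatch: shapes ", paste(rd, collapse = "x"), " vs ",
           paste(dim(imgData(o)), collapse = "x"), call. = FALSE)
    if (max(abs(voxelSpacing(o) - rs)) > 1e-9)
      stop("grid mismatch: differing voxel spacing", call. = FALSE)
  }
  invisible(TRUE)
}

# Shift an array by k voxels along one axis, filling with `fill`.
# out[..., i, ...] = a[..., i - k, ...]
.shiftAxis <- function(a, axis, k, fill = 0) {
  if (k == 0L) return(a)
  d <- dim(a)
  out <- array(fill, dim = d)
  n <- d[axis]
  if (abs(k) >= n) return(out)
  src <- if (k > 0) seq_len(n - k) else seq.int(1 - k, n)
  dst <- if (k > 0) seq.int(1 + k, n) else seq_len(n + k)
  if (axis == 1L) out[dst, , ] <- a[src, , ]
  else if (axis == 2L) out[, dst, ] <- a[, src, ]
  else out[, , dst] <- a[, , src]
  out
}

# One step of 6-connected (face-adjacent) binary dilation.
.dilate6Once <- function(m) {
  out <- m
  for (axis in 1:3) {
    out <- out | .shiftAxis(m, axis, 1L, FALSE) | .shiftAxis(m, axis, -1L, FALSE)
  }
  out
}

# N iterations of 6-connected dilation, optionally clipped to `within`.
.dilate6 <- function(m, iterations, within = NULL) {
  for (i in seq_len(iterations)) {
    m <- .dilate6Once(m)
    if (!is.null(within)) m <- m & within
  }
  if (!is.null(within)) m <- m & within
  m
}

# Separable Gaussian filtering with zero (constant-0) boundary handling.
# Kernel sampled at integer offsets out to 6 sigma and normalized to sum 1,
# so truncation error is negligible (~1e-9 of total mass).
.gaussianFilter3d <- function(a, sigma) {
  r <- max(1L, as.integer(ceiling(6 * sigma)))
  w <- stats::dnorm(seq.int(-r, r), sd = sigma)
  w <- w / sum(w)
  for (axis in 1:3) {
    acc <- a * w[r + 1L]
    for (k in seq_len(r)) {
      acc <- acc + w[r + 1L + k] * (.shiftAxis(a, axis, k) +
                                    .shiftAxis(a, axis, -k))
    }
    a <- acc
  }
  a
}

# Linear index array of voxel coordinates along one axis (1-based).
.axisCoord <- function(d, axis) {
  switch(axis,
         array(rep.int(seq_len(d[1]), d[2] * d[3]), dim = d),
         aperm(array(rep.int(seq_len(d[2]), d[1] * d[3]),
                     dim = d[c(2, 1, 3)]), c(2, 1, 3)),
         aperm(array(rep.int(seq_len(d[3]), d[1] * d[2]),
                     dim = d[c(3, 1, 2)]), c(2, 3, 1)))
}
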