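# Synthetic DWI phantom: mirror-symmetric ellipsoidal brain with symmetric
# ventricle-like CSF blobs and one ellipsoidal ischemic lesion. The trace
# signal follows mono-exponential decay S = S0 exp(-b ADC), the physical
# model of the spin-echo EPI DWI acquisition (b = 1000 s/mm2) the pipeline
# is designed for.

# Evaluate and restore the RNG state around seeded simulation code.
.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

.ellipsoidMask <- function(d, center, radii) {
  x <- .axisCoord(d, 1L); y <- .axisCoord(d, 2L); z <- .axisCoord(d, 3L)
  ((x - center[1]) / radii[1])^2 + ((y - center[2]) / radii[2])^2 +
    ((z - center[3]) / radii[3])^2 <= 1
}

# Brain geometry shared by generateCase and cohort lesion placement.
.phantomGeometry <- function(grid_shape) {
  d <- as.integer(grid_shape)
  bc <- (d + 1) / 2                     # mirror plane between central columns
  A <- 0.42 * d                         # brain semi-axes (voxels)
  vent_dx <- 0.22 * A[1]
  vent_radii <- c(0.10 * A[1], 0.35 * A[2], 0.18 * A[3])
  vent_centers <- rbind(c(bc[1] - vent_dx, bc[2], bc[3] + 0.10 * A[3]),
                        c(bc[1] + vent_dx, bc[2], bc[3] + 0.10 * A[3]))
  list(d = d, bc = bc, A = A, vent_centers = vent_centers,
       vent_radii = vent_radii)
}

.csfMask <- function(geom) {
  .ellipsoidMask(geom$d, geom$vent_centers[1, ], geom$vent_radii) |
    .ellipsoidMask(geom$d, geom$vent_centers[2, ], geom$vent_radii)
}

#' Construct a PhantomSpec
#'
#' Defaults describe one synthetic acute-stroke case on a 2 mm isotropic
#' grid: lesion ADC 500 +/- 60, parenchyma 850 +/- 60, CSF 3000 (all
#' 1e-6 mm2/s), b = 1000 s/mm2, baseline signal 1000 with additive Gaussian
#' noise of sd 20 on b0 and trace. The lesion defaults to a 5-voxel-radius
#' sphere in the right hemisphere.
#'
#' @param grid_shape integer(3); first axis (left-right) must be even.
#' @param spacing_mm numeric(3) voxel size in mm.
#' @param s0_mean baseline signal inside the brain.
#' @param parenchyma_adc_mean,parenchyma_adc_sd parenchymal ADC normal
#'   distribution, 1e-6 mm2/s.
#' @param lesion_adc_mean,lesion_adc_sd lesion ADC normal distribution,
#'   1e-6 mm2/s.
#' @param csf_adc_mean CSF ADC mean, 1e-6 mm2/s.
#' @param lesion_center_vox lesion centre (1-based voxel coordinates);
#'   `NULL` places it mid-right-hemisphere.
#' @param lesion_radii_vox lesion ellipsoid semi-axes in voxels.
#' @param b_value diffusion weighting, s/mm2.
#' @param noise_sd additive Gaussian noise sd on b0 and trace.
#' @param seed integer RNG seed.
#' @return A [PhantomSpec-class].
#' @export
PhantomSpec <- function(grid_shape = c(64L, 76L, 52L), spacing_mm = c(2, 2, 2),
                        s0_mean = 1000,
                        parenchyma_adc_mean = 850, parenchyma_adc_sd = 60,
                        lesion_adc_mean = 500, lesion_adc_sd = 60,
                        csf_adc_mean = 3000,
                        lesion_center_vox = NULL, lesion_radii_vox = c(5, 5, 5),
                        b_value = 1000, noise_sd = 20, seed = 42L) {
  geom <- .phantomGeometry(grid_shape)
  if (is.null(lesion_center_vox))
    lesion_center_vox <- c(geom$bc[1] + 0.5 * geom$A[1], geom$bc[2], geom$bc[3])
  new("PhantomSpec", grid_shape = as.integer(grid_shape),
      spacing_mm = as.numeric(spacing_mm), s0_mean = s0_mean,
      parenchyma_adc_mean = parenchyma_adc_mean,
      parenchyma_adc_sd = parenchyma_adc_sd,
      lesion_adc_mean = lesion_adc_mean, lesion_adc_sd = lesion_adc_sd,
      csf_adc_mean = csf_adc_mean,
      lesion_center_vox = as.numeric(lesion_center_vox),
      lesion_radii_vox = as.numeric(lesion_radii_vox),
      b_value = b_value, noise_sd = noise_sd, seed = as.integer(seed))
}

#' Generate one synthetic DWI case
#'
#' Builds the compartment geometry (brain ellipsoid, symmetric CSF blobs,
#' lesion ellipsoid), draws voxelwise ADC from each compartment's normal
#' distribution (clipped at 0), computes the trace image by the decay law
#' trace = b0 exp(-b ADC 1e-6), and adds Gaussian noise of sd `noise_sd`
#' to b0 and trace inside the brain (clipped at 0).
#'
#' The background (everything except the lesion) ADC field is drawn on one
#' hemisphere and mirrored, so with `noise_sd = 0` the case is exactly
#' mirror-symmetric about the mid-sagittal plane apart from the lesion --
#' the symmetry the contralateral-subtraction step exploits.
#'
#' @param spec a [PhantomSpec-class]; identical spec and seed give
#'   bit-identical output.
#' @param include_lesion set `FALSE` for a lesion-free (fully symmetric)
#'   control case.
#' @return A [PhantomCase-class].
#' @examples
#' case <- generateCase(PhantomSpec(noise_sd = 0, seed = 1))
#' maskVolumeMl(case@truth_lesion)
#' @export
generateCase <- function(spec, include_lesion = TRUE) {
  validObject(spec)
  geom <- .phantomGeometry(spec@grid_shape)
  d <- geom$d
  brain <- .ellipsoidMask(d, geom$bc, geom$A)
  csf <- .csfMask(geom) & brain
  lesion <- if (include_lesion)
    .ellipsoidMask(d, spec@lesion_center_vox, spec@lesion_radii_vox)
  else array(FALSE, dim = d)
  if (include_lesion) {
    if (!any(lesion)) stop("lesion ellipsoid contains no voxels", call. = FALSE)
    if (any(lesion & !brain))
      stop("lesion ellipsoid extends outside the brain", call. = FALSE)
  }

  nx <- d[1]; half <- seq_len(nx %/% 2L)
  mirror_of_half <- seq.int(nx, nx %/% 2L + 1L)
  .withSeed(spec@seed, {
    # background ADC: draw one hemisphere per compartment, mirror it
    adc <- array(0, dim = d)
    compL <- array(0L, dim = c(length(half), d[2], d[3]))
    compL[brain[half, , ]] <- 1L
    compL[csf[half, , ]] <- 2L
    valsL <- array(0, dim = dim(compL))
    np <- sum(compL == 1L); nc <- sum(compL == 2L)
    valsL[compL == 1L] <- stats::rnorm(np, spec@parenchyma_adc_mean,
                                       spec@parenchyma_adc_sd)
    valsL[compL == 2L] <- stats::rnorm(nc, spec@csf_adc_mean,
                                       spec@parenchyma_adc_sd)
    adc[half, , ] <- valsL
    adc[mirror_of_half, , ] <- valsL
    if (include_lesion)
      adc[lesion] <- stats::rnorm(sum(lesion), spec@lesion_adc_mean,
                                  spec@lesion_adc_sd)
    adc[adc < 0] <- 0
    adc[!brain] <- 0

    b0 <- array(0, dim = d)
    b0[brain] <- spec@s0_mean
    trace <- b0 * exp(-spec@b_value * adc * 1e-6)
    if (spec@noise_sd > 0) {
      nb <- sum(brain)
      b0[brain] <- pmax(0, b0[brain] + stats::rnorm(nb, 0, spec@noise_sd))
      trace[brain] <- pmax(0, trace[brain] + stats::rnorm(nb, 0, spec@noise_sd))
    }

    sp <- spec@spacing_mm
    new("PhantomCase",
        b0 = ImageVolume(b0, sp, .INTENSITY_UNITS),
        trace = ImageVolume(trace, sp, .INTENSITY_UNITS),
        adc = ImageVolume(adc, sp, .ADC_UNITS),
        brain_mask = BinaryMask(brain, sp),
        truth_lesion = BinaryMask(lesion, sp),
        spec = spec)
  })
}

# Sphere radius (voxels, per axis) giving a target volume in mL.
.radiiForVolumeMl <- function(volume_ml, spacing_mm) {
  r_mm <- (3 * volume_ml * 1000 / (4 * pi))^(1 / 3)
  r_mm / spacing_mm
}

#' Generate a seeded cohort of synthetic cases
#'
#' Truth lesion volumes are log-uniform over `lesion_volume_range_ml`
#' (solved to sphere radii, so realised volumes match the target up to
#' voxel quantization). Per-case lesion and parenchyma ADC means are
#' jittered by `N(0, adc_jitter)` to create between-subject variability,
#' and lesion centres are placed at random within one hemisphere, strictly
#' inside the brain and clear of the CSF blobs and the mid-sagittal plane.
#' Per-case seeds are derived deterministically from `seed`.
#'
#' @param base_spec a [PhantomSpec-class] providing all non-varied
#'   parameters.
#' @param n number of cases (>= 1).
#' @param lesion_volume_range_ml interval of target truth volumes in mL.
#' @param adc_jitter sd (1e-6 mm2/s) of the per-case jitter on lesion and
#'   parenchyma ADC means.
#' @param seed master seed for the cohort.
#' @return list of [PhantomCase-class] of length `n`.
#' @export
generateCohort <- function(base_spec, n, lesion_volume_range_ml = c(0.2, 20),
                           adc_jitter = 30, seed = base_spec@seed) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  r <- lesion_volume_range_ml
  if (length(r) != 2L || !all(is.finite(r)) || r[1] <= 0 || r[2] < r[1])
    stop("empty or invalid lesion volume range", call. = FALSE)
  geom <- .phantomGeometry(base_spec@grid_shape)
  csf <- .csfMask(geom)
  brain <- .ellipsoidMask(geom$d, geom$bc, geom$A)
  brain_interior <- !.dilate6Once(!brain)
  .withSeed(seed, {
    target_ml <- exp(stats::runif(n, log(r[1]), log(r[2])))
    les_jit <- stats::rnorm(n, 0, adc_jitter)
    par_jit <- stats::rnorm(n, 0, adc_jitter)
    case_seeds <- sample.int(.Machine$integer.max - 1L, n)
    lapply(seq_len(n), function(i) {
      radii <- .radiiForVolumeMl(target_ml[i], base_spec@spacing_mm)
      center <- .placeLesion(geom, radii, csf, brain_interior)
      spec <- base_spec
      spec@lesion_adc_mean <- base_spec@lesion_adc_mean + les_jit[i]
      spec@parenchyma_adc_mean <- base_spec@parenchyma_adc_mean + par_jit[i]
      spec@lesion_center_vox <- center
      spec@lesion_radii_vox <- radii
      spec@seed <- case_seeds[i]
      validObject(spec)
      generateCase(spec)
    })
  })
}

# Rejection-sample a lesion centre: strictly inside the brain (1-voxel
# interior margin), in one hemisphere (clear of the mirror plane), not
# overlapping CSF.
.placeLesion <- function(geom, radii, csf, brain_interior, max_tries = 500L) {
  d <- geom$d; bc <- geom$bc; A <- geom$A
  xlo <- radii[1] + 1.5                 # keep the lesion off the midline
  xhi <- max(xlo, 0.9 * A[1] - radii[1])
  for (try in seq_len(max_tries)) {
    side <- sample(c(-1, 1), 1)
    center <- c(bc[1] + side * stats::runif(1, xlo, xhi),
                bc[2] + stats::runif(1, -0.65, 0.65) * A[2],
                bc[3] + stats::runif(1, -0.65, 0.65) * A[3])
    lesion <- .ellipsoidMask(d, center, radii)
    if (!any(lesion)) next
    if (any(lesion & !brain_interior)) next
    if (any(lesion & csf)) next
    return(center)
  }
  stop("could not place a lesion of the requested size inside the brain",
       call. = FALSE)
}

#' Cohort manifest table
#'
#' @param cases list of [PhantomCase-class] from [generateCohort()].
#' @return data.frame with case id, seed, truth volume (mL) and the
#'   per-case lesion/parenchyma ADC means.
#' @export
cohortManifest <- function(cases) {
  data.frame(
    case = seq_along(cases),
    seed = vapply(cases, function(cs) cs@spec@seed, integer(1)),
    truth_volume_ml = vapply(cases, function(cs) maskVolumeMl(cs@truth_lesion),
                             numeric(1)),
    lesion_adc_mean = vapply(cases, function(cs) cs@spec@lesion_adc_mean,
                             numeric(1)),
    parenchyma_adc_mean = vapply(cases,
                                 function(cs) cs@spec@parenchyma_adc_mean,
                                 numeric(1)))
}
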