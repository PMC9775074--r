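# Diffusion phantom: perpendicular fiber geometry around the lateral
# ventricle body, the configuration the ALPS index relies on. The phantom
# contains a projection-fiber block (principal diffusivity cranio-caudal), an
# association-fiber block (principal diffusivity anterior-posterior), an
# isotropic surround, and background. A perivascular-space component is
# modeled as additive left-right diffusivity in both fiber regions, and
# white-matter-hyperintensity load as a global multiplicative diffusivity
# factor.

REGION_LEVELS <- c("background", "projection", "association",
                   "subcortical_other")

default_region_map <- function(grid_shape) {
  g <- grid_shape
  m <- array(factor("background", levels = REGION_LEVELS), g)
  # isotropic surround occupies the interior
  m[2:(g[1] - 1), 2:(g[2] - 1), 2:(g[3] - 1)] <- "subcortical_other"
  # the two fiber blocks share left-right (x) and cranio-caudal (z) extent
  # and sit side by side along anterior-posterior (y), the arrangement of
  # the projection and association ROIs on one axial slice
  bx <- 4:(g[1] - 3); bz <- 4:(g[3] - 3)
  m[bx, 4:8, bz] <- "projection"
  m[bx, (g[2] - 7):(g[2] - 3), bz] <- "association"
  m
}

#' Specify a diffusion phantom
#'
#' The phantom geometry mirrors the anatomy exploited by the ALPS method:
#' near the body of the lateral ventricle the projection fibers run
#' cranio-caudally (z), the association fibers (superior longitudinal
#' fasciculus) run anterior-posteriorly (y), and the medullary-vein
#' perivascular space runs left-right (x), all mutually perpendicular.
#' `pvs_axis_boost` adds diffusivity along x in both fiber regions
#' (the perivascular water component); `wmh_scale` multiplies every tensor
#' globally (diffuse white-matter-hyperintensity-like elevation).
#'
#' The default `pvs_axis_boost` of 4.56e-4 mm^2/s puts the noiseless ALPS
#' index of the phantom at 1.76, a healthy-range value.
#'
#' @param grid_shape integer length-3 voxel counts per axis.
#' @param voxel_size_mm numeric length-3, mm.
#' @param region_map factor/character array of `grid_shape` with levels
#'   background, projection, association, subcortical_other; `NULL` builds
#'   the default two-block geometry.
#' @param base_tensors named list of 3x3 symmetric positive-definite base
#'   tensors (mm^2/s) for projection, association, subcortical_other,
#'   background.
#' @param pvs_axis_boost additive left-right (xx) diffusivity in the fiber
#'   regions, mm^2/s.
#' @param wmh_scale global multiplicative diffusivity factor, >= 1.
#' @param noise_sigma Rician noise level relative to the b0 signal used when
#'   simulating diffusion volumes from this phantom (default 1/30, i.e.
#'   SNR 30).
#' @param seed integer seed for the simulated acquisition.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(20, 20, 20),
                         voxel_size_mm = c(2, 2, 2.5),
                         region_map = NULL,
                         base_tensors = list(
                           projection        = diag(c(0.6, 0.6, 1.7)) * 1e-3,
                           association       = diag(c(0.6, 1.7, 0.6)) * 1e-3,
                           subcortical_other = diag(3) * 0.8e-3,
                           background        = diag(3) * 0.3e-3),
                         pvs_axis_boost = 4.56e-4,
                         wmh_scale = 1,
                         noise_sigma = 1 / 30,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 12L))
    stop_("grid_shape must be three integers, each >= 12 so that the two 12-voxel ROIs fit")
  if (is.null(region_map)) region_map <- default_region_map(grid_shape)
  region_map <- array(factor(as.character(region_map), levels = REGION_LEVELS),
                      grid_shape)
  if (anyNA(region_map)) stop_("region_map contains labels outside %s",
                               paste(REGION_LEVELS, collapse = ", "))
  missing_regions <- setdiff(REGION_LEVELS, names(base_tensors))
  if (length(missing_regions))
    stop_("base_tensors missing region(s): %s",
          paste(missing_regions, collapse = ", "))
  for (nm in names(base_tensors)) check_spd(base_tensors[[nm]],
                                            paste0(nm, " base tensor"))
  if (!is.numeric(pvs_axis_boost) || pvs_axis_boost < 0)
    stop_("pvs_axis_boost must be a non-negative diffusivity")
  if (!is.numeric(wmh_scale) || wmh_scale < 1)
    stop_("wmh_scale must be >= 1")
  if (!is.numeric(noise_sigma) || noise_sigma < 0)
    stop_("noise_sigma must be >= 0")
  structure(list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 region_map = region_map, base_tensors = base_tensors,
                 pvs_axis_boost = pvs_axis_boost, wmh_scale = wmh_scale,
                 noise_sigma = noise_sigma, seed = seed),
            class = "phantom_spec")
}

#' Generate the tensor field of a phantom
#'
#' Assigns each voxel its region's base tensor, adds `pvs_axis_boost` to the
#' left-right (xx) diagonal element in the projection and association
#' regions, and multiplies every tensor by `wmh_scale`. The background is
#' excluded from the validity mask.
#'
#' @param spec a [phantom_spec()].
#' @return A [tensor_field()].
#' @export
generate_tensor_field <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$grid_shape
  nv <- prod(g)
  Dm <- matrix(0, nv, 6)
  reg <- as.character(spec$region_map)
  for (nm in REGION_LEVELS) {
    v <- tensor_to_vec6(spec$base_tensors[[nm]])
    sel <- which(reg == nm)
    if (length(sel)) Dm[sel, ] <- matrix(v, length(sel), 6, byrow = TRUE)
  }
  fiber <- reg %in% c("projection", "association")
  Dm[fiber, 1] <- Dm[fiber, 1] + spec$pvs_axis_boost
  Dm <- Dm * spec$wmh_scale
  mask <- array(reg != "background", g)
  tensor_field(array(Dm, c(g, 6L)), voxel_size_mm = spec$voxel_size_mm,
               mask = mask)
}

#' Phantom region centroids
#'
#' Voxel (1-based, rounded) centroids of the projection and association
#' regions, convenient as ALPS ROI centers on phantom data.
#'
#' @param spec a [phantom_spec()].
#' @return List with integer voxel triples `projection` and `association`.
#' @export
phantom_region_centers <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  ctr <- function(nm) {
    idx <- which(spec$region_map == nm, arr.ind = TRUE)
    as.integer(round(colMeans(idx)))
  }
  list(projection = ctr("projection"), association = ctr("association"))
}

#' Default diffusion gradient scheme
#'
#' One b = 0 frame followed by `n_dir` single-shell directions spread over
#' the sphere by the golden-angle (Fibonacci) construction, emulating a
#' 32-direction clinical acquisition at b = 1000 s/mm^2.
#'
#' @param n_dir number of diffusion-encoding directions.
#' @param b shell b-value, s/mm^2.
#' @param n_b0 number of b = 0 frames.
#' @return List with `bvals` (length `n_b0 + n_dir`) and `bvecs`
#'   (`(n_b0 + n_dir) x 3`, unit rows for b > 0).
#' @export
dwi_scheme <- function(n_dir = 32L, b = 1000, n_b0 = 1L) {
  stopifnot(n_dir >= 6L, n_b0 >= 1L, b > 0)
  i <- seq_len(n_dir)
  z <- (2 * i - 1) / n_dir - 1
  r <- sqrt(pmax(0, 1 - z^2))
  th <- 2 * pi * i * (sqrt(5) - 1) / 2
  dirs <- cbind(r * cos(th), r * sin(th), z)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  list(bvals = c(rep(0, n_b0), rep(b, n_dir)),
       bvecs = rbind(matrix(0, n_b0, 3), dirs))
}

#' Simulate a diffusion-weighted volume from a tensor field
#'
#' Monoexponential forward model `S = S0 * exp(-b * g' D g)` per gradient,
#' with optional Rician noise: independent Gaussian noise of standard
#' deviation `noise_sigma * s0` is added to the real and imaginary channels
#' and the magnitude taken, the standard model for magnitude MRI.
#'
#' @param tf a [tensor_field()].
#' @param bvals,bvecs gradient table; defaults to [dwi_scheme()] with 32
#'   directions. `bvecs` must have unit-norm rows where `bvals > 0`.
#' @param s0 non-diffusion-weighted signal amplitude.
#' @param noise_sigma Rician noise level relative to `s0`; 0 gives the
#'   noiseless closed-form signal.
#' @param seed integer seed; fixed seed reproduces the volume exactly.
#' @return Object of class `dwi_volume`: list with 4D `signal`, `bvals`,
#'   `bvecs`, `voxel_size_mm`, `axes`.
#' @export
generate_dwi <- function(tf, bvals = NULL, bvecs = NULL, s0 = 1000,
                         noise_sigma = 0, seed = NULL) {
  stopifnot(inherits(tf, "tensor_field"))
  if (is.null(bvals) || is.null(bvecs)) {
    sch <- dwi_scheme()
    bvals <- sch$bvals; bvecs <- sch$bvecs
  }
  bvecs <- as.matrix(bvecs)
  ng <- length(bvals)
  if (nrow(bvecs) != ng || ncol(bvecs) != 3L)
    stop_("bvecs must be an n x 3 matrix matching length(bvals)")
  dwi_check_gradients(bvals, bvecs)
  sp <- dim(tf$mask)
  nv <- prod(sp)
  Dm <- matrix(tf$D, nv, 6)
  # quadratic form g' D g expressed on the six components
  W <- cbind(bvecs[, 1]^2, bvecs[, 2]^2, bvecs[, 3]^2,
             2 * bvecs[, 1] * bvecs[, 2],
             2 * bvecs[, 1] * bvecs[, 3],
             2 * bvecs[, 2] * bvecs[, 3])
  att <- Dm %*% t(W * bvals)         # nv x ng: b * g'Dg
  S <- s0 * exp(-att)
  if (noise_sigma > 0) {
    S <- with_seed(seed, {
      sig <- noise_sigma * s0
      re <- S + matrix(rnorm(nv * ng, sd = sig), nv, ng)
      im <- matrix(rnorm(nv * ng, sd = sig), nv, ng)
      sqrt(re^2 + im^2)
    })
  }
  structure(list(signal = array(S, c(sp, ng)), bvals = bvals, bvecs = bvecs,
                 voxel_size_mm = tf$voxel_size_mm, axes = tf$axes),
            class = "dwi_volume")
}

# shared gradient-table validation
dwi_check_gradients <- function(bvals, bvecs) {
  if (sum(bvals == 0) < 1L) stop_("at least one b = 0 frame is required")
  dw <- bvals > 0
  if (sum(dw) >= 1L) {
    nrm <- sqrt(rowSums(bvecs[dw, , drop = FALSE]^2))
    if (any(abs(nrm - 1) > 1e-6))
      stop_("b-vectors must be unit norm for b > 0 frames")
  }
  # unique up to sign
  dirs <- bvecs[dw, , drop = FALSE]
  dirs <- dirs * sign(dirs[, 3] + (dirs[, 3] == 0) * (dirs[, 2] + (dirs[, 2] == 0) * dirs[, 1]))
  if (nrow(unique(round(dirs, 8))) < 6L)
    stop_("at least 6 unique non-collinear diffusion directions are required; got %d",
          nrow(unique(round(dirs, 8))))
  invisible(TRUE)
}

#' @export
print.dwi_volume <- function(x, ...) {
  sp <- dim(x$signal)
  cat(sprintf("<dwi_volume> %d x %d x %d voxels, %d frames (%d b0, b max %g s/mm^2)\n",
              sp[1], sp[2], sp[3], sp[4], sum(x$bvals == 0), max(x$bvals)))
  invisible(x)
}
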