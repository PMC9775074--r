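# Diffusion tensor fitting by log-linear least squares, and the maps
# derived from the fitted field.

#' Fit diffusion tensors by log-linear least squares
#'
#' Per voxel, solves the ordinary least-squares problem
#' `ln(S_i / S0) = -b_i g_i' D g_i` over the diffusion-weighted frames,
#' the classic dtifit-style linear tensor fit. Multiple b = 0 frames are
#' averaged before the log ratio. Voxels with any non-positive signal are
#' masked out rather than fitted. Negative eigenvalues and negative
#' diagonal elements arising from noise are clamped to zero in the derived
#' maps, with the clamp count reported on the returned field.
#'
#' @param dwi a `dwi_volume`.
#' @param mask optional logical array restricting the fit.
#' @return A [tensor_field()] in the acquisition's axis convention.
#' @export
fit_tensor <- function(dwi, mask = NULL) {
  stopifnot(inherits(dwi, "dwi_volume"))
  dwi_check_gradients(dwi$bvals, dwi$bvecs)
  sp <- dim(dwi$signal)[1:3]
  ng <- dim(dwi$signal)[4]
  if (length(dwi$bvals) != ng)
    stop_("gradient count (%d) does not match 4th signal dimension (%d)",
          length(dwi$bvals), ng)
  b0 <- dwi$bvals == 0
  dw <- !b0
  g <- dwi$bvecs[dw, , drop = FALSE]
  b <- dwi$bvals[dw]
  X <- cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
             2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3],
             2 * g[, 2] * g[, 3]) * b
  qx <- qr(X)
  if (qx$rank < 6L)
    stop_("rank-deficient gradient geometry: %d directions span only rank %d; at least 6 non-collinear directions are required",
          nrow(g), qx$rank)

  nv <- prod(sp)
  S <- matrix(dwi$signal, nv, ng)
  s0 <- if (sum(b0) == 1L) S[, b0] else rowMeans(S[, b0, drop = FALSE])
  fit_mask <- s0 > 0 &
    matrixStats_all_positive(S[, dw, drop = FALSE])
  if (!is.null(mask)) {
    stopifnot(identical(dim(mask), sp))
    fit_mask <- fit_mask & as.vector(mask)
  }
  if (!any(fit_mask)) stop_("no voxel has positive signal in every frame")

  Y <- -log(S[fit_mask, dw, drop = FALSE] / s0[fit_mask])  # nfit x ndw
  # one shared design: D components = pseudo-inverse %*% log-attenuations
  P <- solve(crossprod(X), t(X))                            # 6 x ndw
  Dfit <- Y %*% t(P)                                        # nfit x 6
  Dm <- matrix(NA_real_, nv, 6)
  Dm[fit_mask, ] <- Dfit
  tensor_field(array(Dm, c(sp, 6L)), voxel_size_mm = dwi$voxel_size_mm,
               mask = array(fit_mask, sp), axes = dwi$axes)
}

# rowwise all-positive without allocating a logical matrix per column
matrixStats_all_positive <- function(M) {
  ok <- rep(TRUE, nrow(M))
  for (j in seq_len(ncol(M))) ok <- ok & M[, j] > 0
  ok
}

#' Direction-encoded color FA volume
#'
#' Radiological DEC convention: red = left-right, green =
#' anterior-posterior, blue = cranio-caudal; each channel is the absolute
#' principal-direction component scaled by FA, so isotropic voxels are
#' black, cranio-caudal projection fibers blue and anterior-posterior
#' association fibers green.
#'
#' @param tf a fitted [tensor_field()].
#' @return Numeric array `c(dim, 3)` with values in \[0, 1\], `NA` outside
#'   the mask.
#' @export
color_fa <- function(tf) {
  stopifnot(inherits(tf, "tensor_field"))
  sp <- dim(tf$mask)
  pd <- matrix(tf$principal_direction, prod(sp), 3)
  rgb <- abs(pd) * as.vector(tf$fa)
  array(rgb, c(sp, 3L))
}

#' Axis-aligned diffusivity maps
#'
#' The diagonal elements of the fitted tensor in the named anatomical axis
#' frame — Dxx along left-right, Dyy along anterior-posterior, Dzz along
#' cranio-caudal. These are matrix elements, not eigenvalues: in a voxel
#' whose fibers are oblique to the axes they differ from the tensor's
#' principal diffusivities, which is exactly the property the ALPS index
#' uses.
#'
#' @param tf a fitted [tensor_field()].
#' @return Named list of three 3D arrays `dxx`, `dyy`, `dzz` (mm^2/s).
#' @export
axis_diffusivity_maps <- function(tf) {
  stopifnot(inherits(tf, "tensor_field"))
  if (is.null(tf$axes) || !identical(names(tf$axes), c("x", "y", "z")))
    stop_("tensor field lacks its axis convention; cannot name the maps")
  list(dxx = tf$dxx, dyy = tf$dyy, dzz = tf$dzz)
}
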