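# Tensor-field container and shared symmetric-tensor arithmetic.
#
# A diffusion tensor is stored as its six unique components in the fixed
# order (xx, yy, zz, xy, xz, yz), units mm^2/s. The array axis convention
# throughout the package is anatomical: x = left-right, y =
# anterior-posterior, z = cranio-caudal.

TENSOR_COMPONENTS <- c("xx", "yy", "zz", "xy", "xz", "yz")

AXIS_CONVENTION <- c(x = "left-right", y = "anterior-posterior",
                     z = "cranio-caudal")

# 3x3 symmetric matrix -> length-6 component vector
tensor_to_vec6 <- function(D) {
  c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
}

# length-6 component vector -> 3x3 symmetric matrix
vec6_to_tensor <- function(v) {
  matrix(c(v[1], v[4], v[5],
           v[4], v[2], v[6],
           v[5], v[6], v[3]), 3, 3)
}

check_spd <- function(D, what = "tensor") {
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-10)))
    stop_("%s must be symmetric", what)
  ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0))
    stop_("%s must be positive-definite (eigenvalues: %s)",
          what, paste(signif(ev, 4), collapse = ", "))
  invisible(TRUE)
}

# Closed-form fractional anisotropy of three eigenvalues.
fa_from_eigenvalues <- function(ev) {
  ss <- sum(ev^2)
  if (ss <= 0) return(0)
  mn <- mean(ev)
  fa <- sqrt(3 / 2) * sqrt(sum((ev - mn)^2) / ss)
  min(max(fa, 0), 1)
}

#' Construct a tensor field from per-voxel tensor components
#'
#' A `tensor_field` holds a per-voxel symmetric diffusion tensor together
#' with the maps derived from it: fractional anisotropy (FA), the principal
#' diffusion direction, and the diagonal diffusivities along the anatomical
#' axes (x = left-right, y = anterior-posterior, z = cranio-caudal). The
#' diagonal maps are tensor matrix elements in the named axis frame, not
#' eigenvalues.
#'
#' Negative eigenvalues (possible after fitting noisy data) are clamped to
#' zero for the FA map, and negative diagonal elements are clamped to zero
#' for the diffusivity maps; the total number of clamped voxels is recorded
#' in `$n_clamped`.
#'
#' @param D numeric array `c(dim, 6)`: per-voxel tensor components in the
#'   order xx, yy, zz, xy, xz, yz (mm^2/s).
#' @param voxel_size_mm numeric length-3 voxel edge lengths.
#' @param mask logical array of the spatial dimensions; voxels outside the
#'   mask carry `NA` derived maps.
#' @param axes named character vector mapping array axes to anatomical
#'   directions; the package convention is
#'   `c(x = "left-right", y = "anterior-posterior", z = "cranio-caudal")`.
#' @return An object of class `tensor_field` with elements `D`, `fa`,
#'   `dxx`, `dyy`, `dzz`, `principal_direction`, `mask`, `voxel_size_mm`,
#'   `axes`, `n_clamped`.
#' @export
tensor_field <- function(D, voxel_size_mm = c(2, 2, 2.5), mask = NULL,
                         axes = AXIS_CONVENTION) {
  dims <- dim(D)
  if (length(dims) != 4L || dims[4] != 6L)
    stop_("D must be a 4D array with 6 tensor components on the last axis")
  sp <- dims[1:3]
  if (is.null(mask)) mask <- array(TRUE, sp)
  stopifnot(identical(dim(mask), sp))
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stop_("voxel_size_mm must be three positive lengths")
  if (!identical(names(axes), c("x", "y", "z")))
    stop_("axes must be a named character vector with names x, y, z")

  nv <- prod(sp)
  Dm <- matrix(D, nv, 6)
  fa <- rep(NA_real_, nv)
  pd <- matrix(NA_real_, nv, 3)
  n_clamped <- 0L
  idx <- which(as.vector(mask))
  for (i in idx) {
    e <- eigen(vec6_to_tensor(Dm[i, ]), symmetric = TRUE)
    ev <- e$values
    if (any(ev < 0)) n_clamped <- n_clamped + 1L
    ev <- pmax(ev, 0)
    fa[i] <- fa_from_eigenvalues(ev)
    pd[i, ] <- e$vectors[, 1L]
  }
  diag_clamp <- function(k) {
    v <- rep(NA_real_, nv)
    v[idx] <- Dm[idx, k]
    neg <- which(v < 0)
    n_clamped <<- n_clamped + length(neg)
    v[neg] <- 0
    array(v, sp)
  }
  structure(list(
    D = D,
    fa = array(fa, sp),
    dxx = diag_clamp(1L),
    dyy = diag_clamp(2L),
    dzz = diag_clamp(3L),
    principal_direction = array(pd, c(sp, 3L)),
    mask = mask,
    voxel_size_mm = voxel_size_mm,
    axes = axes,
    n_clamped = n_clamped
  ), class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  sp <- dim(x$mask)
  cat(sprintf("<tensor_field> %d x %d x %d voxels (%s mm), %d in mask\n",
              sp[1], sp[2], sp[3],
              paste(format(x$voxel_size_mm), collapse = " x "),
              sum(x$mask)))
  cat(sprintf("  axes: x=%s, y=%s, z=%s\n", x$axes["x"], x$axes["y"],
              x$axes["z"]))
  fa <- x$fa[x$mask]
  cat(sprintf("  FA: median %.3f, range [%.3f, %.3f]; %d voxel value(s) clamped\n",
              median(fa), min(fa), max(fa), x$n_clamped))
  invisible(x)
}
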