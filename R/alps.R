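# ALPS index: paired spherical ROIs on the projection and association
# fibers beside the lateral ventricle, and the diffusivity ratio
#   ALPS = mean(Dx-proj, Dx-asso) / mean(Dy-proj, Dz-asso),
# i.e. diffusion along the left-right perivascular axis over diffusion
# perpendicular to both the fibers and the perivascular space. Because any
# global diffusivity elevation (e.g. white-matter hyperintensity load)
# multiplies numerator and denominator alike, the ratio cancels it.

#' Specify a spherical ROI
#'
#' @param center integer voxel triple (1-based array indices).
#' @param n target voxel count (default 12, the conventional ALPS ROI
#'   size).
#' @param fiber `"projection"` or `"association"`.
#' @return List of class `roi_spec`.
#' @export
roi_spec <- function(center, n = 12L, fiber = c("projection", "association")) {
  fiber <- match.arg(fiber)
  center <- as.integer(center)
  if (length(center) != 3L || anyNA(center))
    stop_("center must be three voxel indices")
  n <- as.integer(n)
  if (n < 1L) stop_("ROI voxel count must be positive")
  structure(list(center = center, n = n, fiber = fiber), class = "roi_spec")
}

#' Deterministic n-voxel spherical ROI
#'
#' No lattice sphere contains exactly 12 voxels for a generic radius, so
#' the "spherical ROI containing 12 voxels" is resolved deterministically:
#' candidate voxels are ordered by squared Euclidean distance from the
#' center (in voxel units), ties broken lexicographically by (x, y, z)
#' index, and the first `n` are taken. An ROI that would cross the volume
#' boundary is an error — it is never silently truncated.
#'
#' @param spec a [roi_spec()] (or bare integer center triple).
#' @param volume_shape integer length-3 volume dimensions.
#' @return Integer matrix `n x 3` of voxel indices, one row per voxel, in
#'   selection order.
#' @export
sphere_roi <- function(spec, volume_shape) {
  if (!inherits(spec, "roi_spec")) spec <- roi_spec(spec)
  volume_shape <- as.integer(volume_shape)
  r <- max(1L, ceiling((3 * spec$n / (4 * pi))^(1 / 3)) + 1L)
  off <- as.matrix(expand.grid(x = -r:r, y = -r:r, z = -r:r))
  d2 <- rowSums(off^2)
  ord <- order(d2, off[, 1], off[, 2], off[, 3])
  if (spec$n > nrow(off))
    stop_("ROI voxel count %d exceeds the search neighborhood", spec$n)
  sel <- off[ord[seq_len(spec$n)], , drop = FALSE]
  vox <- sweep(sel, 2, spec$center, "+")
  out_of_bounds <- vox < 1L | vox > matrix(volume_shape, nrow(vox), 3,
                                           byrow = TRUE)
  if (any(out_of_bounds))
    stop_("ROI at center (%s) is clipped by the volume boundary (%d voxel(s) outside %s); move the center inward",
          paste(spec$center, collapse = ", "), sum(rowSums(out_of_bounds) > 0),
          paste(volume_shape, collapse = " x "))
  dimnames(vox) <- NULL
  storage.mode(vox) <- "integer"
  vox
}

#' Measure the ALPS index
#'
#' Averages the axis diffusivities over the two ROIs — Dxx and Dyy over the
#' projection-fiber ROI, Dxx and Dzz over the association-fiber ROI — and
#' forms
#' `alps_index = mean(dx_proj, dx_asso) / mean(dy_proj, dz_asso)`.
#' Every ROI voxel must lie inside the field's validity mask; a zero
#' denominator is a degenerate-measurement error.
#'
#' @param tf a fitted [tensor_field()].
#' @param roi_proj,roi_asso [roi_spec()]s (or center triples) for the
#'   projection and association ROIs.
#' @return Object of class `alps_measurement` with the four ROI-mean
#'   diffusivities, `alps_index`, and the ROI voxel counts.
#' @export
measure_alps <- function(tf, roi_proj, roi_asso) {
  stopifnot(inherits(tf, "tensor_field"))
  if (!inherits(roi_proj, "roi_spec"))
    roi_proj <- roi_spec(roi_proj, fiber = "projection")
  if (!inherits(roi_asso, "roi_spec"))
    roi_asso <- roi_spec(roi_asso, fiber = "association")
  sp <- dim(tf$mask)
  vox_p <- sphere_roi(roi_proj, sp)
  vox_a <- sphere_roi(roi_asso, sp)
  check_in_mask <- function(vox, what) {
    inmask <- tf$mask[vox]
    if (!all(inmask)) {
      bad <- vox[!inmask, , drop = FALSE]
      stop_("%s ROI contains %d masked voxel(s): %s", what, nrow(bad),
            paste(apply(bad, 1, paste, collapse = ","), collapse = "; "))
    }
  }
  check_in_mask(vox_p, "projection")
  check_in_mask(vox_a, "association")
  dx_proj <- mean(tf$dxx[vox_p])
  dy_proj <- mean(tf$dyy[vox_p])
  dx_asso <- mean(tf$dxx[vox_a])
  dz_asso <- mean(tf$dzz[vox_a])
  denom <- mean(c(dy_proj, dz_asso))
  if (!is.finite(denom) || denom <= 0)
    stop_("degenerate ALPS measurement: perpendicular diffusivity mean is %g",
          denom)
  structure(list(dx_proj = dx_proj, dy_proj = dy_proj, dx_asso = dx_asso,
                 dz_asso = dz_asso,
                 alps_index = mean(c(dx_proj, dx_asso)) / denom,
                 roi_voxel_counts = c(projection = nrow(vox_p),
                                      association = nrow(vox_a)),
                 centers = list(projection = roi_proj$center,
                                association = roi_asso$center)),
            class = "alps_measurement")
}

#' @export
print.alps_measurement <- function(x, ...) {
  cat("<alps_measurement>\n")
  cat(sprintf("  Dx-proj %.4g  Dy-proj %.4g  (projection ROI, %d voxels at %s)\n",
              x$dx_proj, x$dy_proj, x$roi_voxel_counts["projection"],
              paste(x$centers$projection, collapse = ",")))
  cat(sprintf("  Dx-asso %.4g  Dz-asso %.4g  (association ROI, %d voxels at %s)\n",
              x$dx_asso, x$dz_asso, x$roi_voxel_counts["association"],
              paste(x$centers$association, collapse = ",")))
  cat(sprintf("  ALPS index = %.4f\n", x$alps_index))
  invisible(x)
}

#' Suggest ROI centers from the color FA map
#'
#' An automated stand-in for manual ROI placement: the projection candidate
#' is the voxel maximizing blue-channel intensity times FA within the
#' search slab; the association candidate maximizes the green channel at
#' the same left-right (x) and cranio-caudal (z) coordinates — "parallel"
#' placement in the same axial plane, shifted anterior-posteriorly. Ties
#' break to the lowest lexicographic voxel. Suggestions should be reviewed
#' before use; manual centers remain the primary interface.
#'
#' @param tf a fitted [tensor_field()].
#' @param fa_floor minimum FA for a candidate voxel (default 0.2).
#' @param z_slab optional integer range restricting the cranio-caudal
#'   search.
#' @return List of two [roi_spec()]s, `projection` and `association`.
#' @export
suggest_roi_centers <- function(tf, fa_floor = 0.2, z_slab = NULL) {
  stopifnot(inherits(tf, "tensor_field"))
  rgb <- color_fa(tf)
  sp <- dim(tf$mask)
  blue <- rgb[, , , 3] * tf$fa
  green <- rgb[, , , 2] * tf$fa
  keep <- array(TRUE, sp)
  if (!is.null(z_slab)) {
    keep[] <- FALSE
    keep[, , z_slab] <- TRUE
  }
  elig <- tf$mask & !is.na(tf$fa) & tf$fa >= fa_floor & keep
  if (!any(elig))
    stop_("no voxel exceeds the FA floor of %g in the search region", fa_floor)
  pick_max <- function(score, eligible) {
    score[!eligible] <- -Inf
    best <- max(score)
    if (!is.finite(best) || best <= 0) return(NULL)
    cand <- which(score == best, arr.ind = TRUE)
    cand <- cand[order(cand[, 1], cand[, 2], cand[, 3]), , drop = FALSE]
    as.integer(cand[1, ])
  }
  proj <- pick_max(blue, elig)
  if (is.null(proj))
    stop_("no projection-fiber candidate exceeds the FA floor of %g", fa_floor)
  same_line <- elig
  same_line[] <- FALSE
  same_line[proj[1], , proj[3]] <- elig[proj[1], , proj[3]]
  asso <- pick_max(green, same_line)
  if (is.null(asso))
    stop_("no association-fiber candidate at x = %d, z = %d exceeds the FA floor of %g",
          proj[1], proj[3], fa_floor)
  list(projection = roi_spec(proj, fiber = "projection"),
       association = roi_spec(asso, fiber = "association"))
}
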