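# Shared fixture builders; everything is generated in code.

# small two-region phantom for fast imaging tests
small_phantom <- function(...) {
  phantom_spec(grid_shape = c(16, 16, 16), ...)
}

# single-voxel tensor field holding one given 3x3 tensor
one_voxel_field <- function(D) {
  arr <- array(alpskit:::tensor_to_vec6(D), c(1, 1, 1, 6))
  tensor_field(arr, voxel_size_mm = c(2, 2, 2))
}

# uniform field of one tensor on a small grid
uniform_field <- function(D, g = c(8, 8, 8)) {
  v <- alpskit:::tensor_to_vec6(D)
  arr <- array(rep(v, each = prod(g)), c(g, 6))
  tensor_field(arr, voxel_size_mm = c(2, 2, 2))
}

# random SPD tensor with diffusivity-scale eigenvalues
random_spd_tensor <- function() {
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  ev <- sort(runif(3, 0.2e-3, 2e-3), decreasing = TRUE)
  R %*% diag(ev) %*% t(R)
}

# random rotation matrix (det +1)
random_rotation <- function() {
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# hand-sized cohort with all raw-score columns, for scoring tests
tiny_cohort <- function() {
  data.frame(
    id = c("a", "b", "c", "d"),
    group = factor(c("NC", "CSVD-non-CI", "CSVD-MCI", "CSVD-VaD"),
                   levels = alpskit:::GROUP_LEVELS),
    wms_vr_dr = c(12, 10, 6, 2), avlt_dr = c(10, 9, 5, 2),
    bnt = c(28, 26, 22, 16), cvf = c(52, 48, 38, 24),
    tmt_a = c(30, 40, 60, 90), tmt_b = c(70, 90, 140, 200),
    scwt_b = c(50, 60, 80, 100), scwt_c = c(70, 85, 110, 140),
    cdt = c(28, 27, 22, 12), vrt = c(13, 12, 8, 4),
    stringsAsFactors = FALSE)
}

# direct simulation of the three-variable mediation chain with known paths
chain_data <- function(n, a, b, c_prime, sd_m = 0, sd_y = 0) {
  x <- rnorm(n)
  m <- a * x + rnorm(n, 0, sd_m)
  y <- b * m + c_prime * x + rnorm(n, 0, sd_y)
  data.frame(x = x, m = m, y = y)
}
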