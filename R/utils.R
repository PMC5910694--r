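#' @keywords internal
"_PACKAGE"

# Vector helpers ---------------------------------------------------------

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-300) stop("cannot normalise a zero-length vector")
  v / n
}

# Any orthonormal pair completing `v` to a right-handed basis.
# Deterministic: reference axis is the coordinate axis least aligned with v.
orthonormal_complement <- function(v) {
  v <- unit(v)
  ref <- diag(3)[, which.min(abs(v))]
  u2 <- unit(ref - sum(ref * v) * v)
  u3 <- c(
    v[2] * u2[3] - v[3] * u2[2],
    v[3] * u2[1] - v[1] * u2[3],
    v[1] * u2[2] - v[2] * u2[1]
  )
  cbind(u2, u3)
}

cross3 <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Round half away from zero
#'
#' Report-table rounding: 0.05 rounds to 0.1 (and -0.05 to -0.1), unlike
#' [base::round()]'s round-half-even. Used for all printed summary tables.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Affine helpers ---------------------------------------------------------
# Convention: 0-based voxel indices, world = affine %*% c(i, j, k, 1),
# index (i, j, k) addressing the voxel CENTRE.

#' Build a diagonal voxel-to-world affine
#'
#' @param voxel_size mm per axis (length 3)
#' @param origin world position of the centre of voxel (0, 0, 0)
#' @return 4x4 affine matrix
#' @export
affine_from_spacing <- function(voxel_size, origin = voxel_size / 2) {
  stopifnot(length(voxel_size) == 3, all(voxel_size > 0))
  a <- diag(4)
  a[1:3, 1:3] <- diag(voxel_size)
  a[1:3, 4] <- origin
  a
}

# continuous 0-based voxel coordinates of world points (points: n x 3)
world_to_voxel <- function(affine, points) {
  points <- matrix(points, ncol = 3)
  inv <- solve(affine)
  t(inv[1:3, 1:3] %*% t(points) + inv[1:3, 4])
}

voxel_to_world <- function(affine, ijk) {
  ijk <- matrix(ijk, ncol = 3)
  t(affine[1:3, 1:3] %*% t(ijk) + affine[1:3, 4])
}

# voxel (1-based array index) containing each world point; "inside" means
# the point falls in the half-open cell centred on the voxel centre
containing_voxel <- function(affine, points) {
  ci <- world_to_voxel(affine, points)
  floor(ci + 0.5) + 1
}

# world coordinates of all voxel centres, as an n x 3 matrix in array order
grid_centres <- function(shape, affine) {
  ijk <- as.matrix(expand.grid(
    i = seq_len(shape[1]) - 1,
    j = seq_len(shape[2]) - 1,
    k = seq_len(shape[3]) - 1
  ))
  voxel_to_world(affine, ijk)
}

# Trilinear interpolation ------------------------------------------------

# Sample a 3D array at continuous 0-based voxel coordinates (single point).
# Returns NA if the 2x2x2 neighbourhood leaves the grid.
trilinear <- function(arr, ci) {
  d <- dim(arr)
  i0 <- floor(ci)
  f <- ci - i0
  i0 <- i0 + 1  # to 1-based corner
  if (any(i0 < 1) || any(i0 + 1 > d)) return(NA_real_)
  w <- c(
    (1 - f[1]) * (1 - f[2]) * (1 - f[3]),
    f[1] * (1 - f[2]) * (1 - f[3]),
    (1 - f[1]) * f[2] * (1 - f[3]),
    f[1] * f[2] * (1 - f[3]),
    (1 - f[1]) * (1 - f[2]) * f[3],
    f[1] * (1 - f[2]) * f[3],
    (1 - f[1]) * f[2] * f[3],
    f[1] * f[2] * f[3]
  )
  v <- c(
    arr[i0[1], i0[2], i0[3]],
    arr[i0[1] + 1, i0[2], i0[3]],
    arr[i0[1], i0[2] + 1, i0[3]],
    arr[i0[1] + 1, i0[2] + 1, i0[3]],
    arr[i0[1], i0[2], i0[3] + 1],
    arr[i0[1] + 1, i0[2], i0[3] + 1],
    arr[i0[1], i0[2] + 1, i0[3] + 1],
    arr[i0[1] + 1, i0[2] + 1, i0[3] + 1]
  )
  sum(w * v)
}

# Shift a 3D logical array by (di, dj, dk), padding with `fill`.
shift3 <- function(arr, di, dj, dk, fill = FALSE) {
  d <- dim(arr)
  out <- array(fill, d)
  lo <- pmax(1, 1 - c(di, dj, dk))
  hi <- pmin(d, d - c(di, dj, dk))
  if (any(hi < lo)) return(out)  # shift moves everything off-grid
  src_i <- lo[1]:hi[1]
  src_j <- lo[2]:hi[2]
  src_k <- lo[3]:hi[3]
  out[src_i + di, src_j + dj, src_k + dk] <- arr[src_i, src_j, src_k]
  out
}

# Chebyshev dilation of a logical mask by radius 1 (26-neighbourhood).
dilate_chebyshev1 <- function(mask) {
  out <- mask
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
    if (di == 0 && dj == 0 && dk == 0) next
    out <- out | shift3(mask, di, dj, dk)
  }
  out
}
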