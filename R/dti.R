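# Diffusion-tensor fitting and eigen-decomposition maps.
#
# Tensor components are stored in the order (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)
# as the 4th dimension of a [nx, ny, nz, 6] array, in mm^2/s.

#' Construct a tensor volume
#'
#' @param D `[nx, ny, nz, 6]` array of tensor components
#'   (xx, yy, zz, xy, xz, yz), mm^2/s
#' @param affine 4x4 voxel-to-world matrix (mm)
#' @param mask 3D logical array of valid voxels (default: all)
#' @return object of class `myo_tensor_volume`
#' @export
tensor_volume <- function(D, affine, mask = NULL) {
  d <- dim(D)
  stopifnot(length(d) == 4, d[4] == 6)
  if (abs(det(affine)) < 1e-12) stop("affine is singular")
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  stopifnot(identical(dim(mask), d[1:3]))
  structure(list(D = D, affine = affine, mask = mask),
            class = "myo_tensor_volume")
}

#' @export
print.myo_tensor_volume <- function(x, ...) {
  d <- dim(x$D)
  cat(sprintf("<myo_tensor_volume> %d x %d x %d, %d masked voxels\n",
              d[1], d[2], d[3], sum(x$mask)))
  invisible(x)
}

# design matrix row per direction g: exponent = b * (x' row), with tensor
# component order (xx, yy, zz, xy, xz, yz)
tensor_design_matrix <- function(directions) {
  g <- matrix(directions, ncol = 3)
  cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
        2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3])
}

#' Fit diffusion tensors by log-linear least squares
#'
#' Per voxel, solves \eqn{\log(S_k/S_0) = -b\, g_k^T D g_k} in the
#' least-squares sense. Voxels with any non-positive signal are excluded
#' from the output mask.
#'
#' @param dwi 4D array of diffusion-weighted volumes (last dim = direction)
#' @param b_value diffusion weighting (s/mm^2)
#' @param directions n x 3 matrix of gradient directions (>= 6,
#'   non-coplanar)
#' @param b0 3D array of unweighted (b = 0) signal
#' @param affine 4x4 voxel-to-world matrix
#' @param mask optional 3D logical array restricting the fit
#' @param smooth_fwhm optional Gaussian smoothing FWHM (mm) applied to the
#'   fitted tensor components (0 = off; intended for noisy fixtures only)
#' @return a [tensor_volume()]
#' @export
fit_tensor <- function(dwi, b_value, directions, b0, affine,
                       mask = NULL, smooth_fwhm = 0) {
  d <- dim(dwi)
  stopifnot(length(d) == 4)
  shape <- d[1:3]
  directions <- matrix(directions, ncol = 3)
  if (nrow(directions) < 6) stop("at least 6 gradient directions are required")
  if (nrow(directions) != d[4]) stop("directions do not match DWI volumes")
  X <- tensor_design_matrix(directions)
  if (qr(X)$rank < 6) stop("singular design matrix: gradient directions are coplanar")
  nvox <- prod(shape)
  S <- matrix(dwi, nvox, d[4])
  s0v <- as.vector(b0)
  if (is.null(mask)) mask <- array(TRUE, shape)
  ok <- as.vector(mask) & s0v > 0 & apply(S > 0, 1, all)
  Y <- -log(S[ok, , drop = FALSE] / s0v[ok]) / b_value  # nvox_ok x ndir
  # D components = (X'X)^-1 X' y, all voxels at once
  coef <- t(solve(crossprod(X), crossprod(X, t(Y))))    # nvox_ok x 6
  Dmat <- matrix(0, nvox, 6)
  Dmat[ok, ] <- coef
  D <- array(Dmat, dim = c(shape, 6))
  if (smooth_fwhm > 0) {
    sigma_mm <- smooth_fwhm / (2 * sqrt(2 * log(2)))
    spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
    for (comp in 1:6) {
      D[, , , comp] <- gaussian_smooth3(D[, , , comp], sigma_mm / spacing)
    }
  }
  tensor_volume(D, affine, mask = array(ok, shape))
}

# separable Gaussian smoothing, sigma in voxel units per axis
gaussian_smooth3 <- function(arr, sigma_vox) {
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(-r:r, sd = s)
    k <- k / sum(k)
    acc <- array(0, dim(arr))
    for (i in seq_along(k)) {
      off <- c(0L, 0L, 0L)
      off[ax] <- (-r:r)[i]
      acc <- acc + k[i] * shift3_replicate(arr, off[1], off[2], off[3])
    }
    arr <- acc
  }
  arr
}

# shift with edge replication (numeric arrays)
shift3_replicate <- function(arr, di, dj, dk) {
  d <- dim(arr)
  idx <- function(n, s) pmin(pmax(seq_len(n) - s, 1L), n)
  arr[idx(d[1], di), idx(d[2], dj), idx(d[3], dk)]
}

#' Eigen-decomposition, FA and MD maps
#'
#' Sorted eigen-decomposition per masked voxel. FA uses
#' \eqn{\sqrt{\tfrac12[(\lambda_1-\lambda_2)^2 + (\lambda_2-\lambda_3)^2 +
#' (\lambda_3-\lambda_1)^2] / (\lambda_1^2+\lambda_2^2+\lambda_3^2)}};
#' negative eigenvalues (possible under noise) are clamped to zero for the
#' FA computation only and the voxel is flagged. Voxels with non-finite
#' tensor components are dropped from the mask and counted.
#'
#' @param tensors a [tensor_volume()]
#' @return object of class `myo_eigen_maps`: arrays `lambda1..3`, `fa`,
#'   `md`, 4D arrays `e1`, `e2`, `e3`, logical `mask`, `n_clamped`,
#'   `n_dropped`
#' @export
eigen_maps <- function(tensors) {
  stopifnot(inherits(tensors, "myo_tensor_volume"))
  shape <- dim(tensors$D)[1:3]
  nvox <- prod(shape)
  Dmat <- matrix(tensors$D, nvox, 6)
  maskv <- as.vector(tensors$mask)
  finite <- apply(is.finite(Dmat), 1, all)
  dropped <- maskv & !finite
  maskv <- maskv & finite
  lam <- matrix(0, nvox, 3)
  E1 <- matrix(0, nvox, 3)
  E2 <- matrix(0, nvox, 3)
  E3 <- matrix(0, nvox, 3)
  vox <- which(maskv)
  for (v in vox) {
    Dm <- matrix(c(
      Dmat[v, 1], Dmat[v, 4], Dmat[v, 5],
      Dmat[v, 4], Dmat[v, 2], Dmat[v, 6],
      Dmat[v, 5], Dmat[v, 6], Dmat[v, 3]
    ), 3, 3)
    ed <- eigen(Dm, symmetric = TRUE)  # descending eigenvalues
    lam[v, ] <- ed$values
    E1[v, ] <- ed$vectors[, 1]
    E2[v, ] <- ed$vectors[, 2]
    E3[v, ] <- ed$vectors[, 3]
  }
  clamped <- maskv & lam[, 3] < 0
  lam_fa <- pmax(lam, 0)
  num <- (lam_fa[, 1] - lam_fa[, 2])^2 + (lam_fa[, 2] - lam_fa[, 3])^2 +
    (lam_fa[, 3] - lam_fa[, 1])^2
  den <- rowSums(lam_fa^2)
  fa <- sqrt(pmax(0, 0.5 * num / pmax(den, 1e-300)))
  fa[!maskv] <- 0
  md <- rowMeans(lam)
  md[!maskv] <- 0
  structure(list(
    lambda1 = array(lam[, 1], shape),
    lambda2 = array(lam[, 2], shape),
    lambda3 = array(lam[, 3], shape),
    e1 = array(E1, c(shape, 3)),
    e2 = array(E2, c(shape, 3)),
    e3 = array(E3, c(shape, 3)),
    fa = array(fa, shape),
    md = array(md, shape),
    mask = array(maskv, shape),
    affine = tensors$affine,
    n_clamped = sum(clamped),
    n_dropped = sum(dropped)
  ), class = "myo_eigen_maps")
}

#' @export
print.myo_eigen_maps <- function(x, ...) {
  cat(sprintf(
    "<myo_eigen_maps> %s voxels masked; FA range %.3f-%.3f; %d clamped, %d dropped\n",
    format(sum(x$mask)), min(x$fa[x$mask]), max(x$fa[x$mask]),
    x$n_clamped, x$n_dropped
  ))
  invisible(x)
}

#' Direction-encoded colour map of the primary eigenvector
#'
#' Per voxel, RGB = |e1| components scaled by FA (sign-invariant), the
#' conventional fibre-orientation colour coding.
#'
#' @param em a [eigen_maps()] result
#' @return `[nx, ny, nz, 3]` array with values in `[0, 1]`
#' @export
primary_eigenvector_rgb <- function(em) {
  stopifnot(inherits(em, "myo_eigen_maps"))
  rgb <- abs(em$e1)
  for (ch in 1:3) rgb[, , , ch] <- rgb[, , , ch] * pmin(em$fa, 1)
  rgb
}
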