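# Synthetic pennate-muscle phantom with analytically known architecture.
#
# Compartments are idealised slabs between two parallel aponeurosis planes.
# Within a slab the fascicle field is either straight (constant direction at
# a prescribed pennation to the long axis) or a family of circular arcs of
# prescribed radius. The slab's end-caps are cut parallel to the fascicle
# direction so that every fascicle runs aponeurosis-to-aponeurosis and the
# analytic ground truth (length, pennation, curvature, volume, PCSA) is
# exact.

#' Electrostatically spread hemisphere gradient scheme (16 directions)
#'
#' Sixteen unit vectors on the upper hemisphere obtained by minimising the
#' antipodally symmetric electrostatic energy; the tensor design matrix of
#' this scheme has rank 6 (condition number 1.56). Frozen so phantoms are
#' reproducible; any >= 6-direction non-coplanar scheme may be substituted.
#'
#' @return 16 x 3 matrix of unit direction vectors
#' @export
default_gradients <- function() {
  m <- rbind(
    c(-0.396527, 0.601445, 0.693564),
    c(-0.896391, 0.182443, 0.403977),
    c(0.716650, 0.301462, 0.628914),
    c(-0.095970, 0.980900, 0.169190),
    c(-0.219676, -0.897557, 0.382274),
    c(0.904767, -0.302940, 0.299371),
    c(0.592012, 0.795500, 0.129235),
    c(0.105700, 0.181529, 0.977688),
    c(-0.680481, 0.720852, 0.131600),
    c(-0.083771, -0.496995, 0.863700),
    c(-0.496842, -0.007049, 0.867813),
    c(0.959642, 0.278866, 0.036347),
    c(-0.703098, -0.496431, 0.509127),
    c(0.232017, 0.720020, 0.654018),
    c(0.516810, -0.280212, 0.808943),
    c(0.410080, -0.796414, 0.444477)
  )
  m / sqrt(rowSums(m^2))
}

#' Specify a phantom compartment
#'
#' A slab between two parallel aponeurosis planes (normal `normal`,
#' separation `thickness_mm`), with in-plane extent `extent_mm[1]` along the
#' cap direction and `extent_mm[2]` along the third axis. Fascicles run at
#' `pennation_deg` to `long_axis`, straight when `arc_radius_mm = Inf` or as
#' circular arcs of that radius otherwise. End-caps are parallel to the
#' fascicle direction, so fascicles always attach on the aponeurosis planes.
#'
#' @param label positive integer compartment label
#' @param pennation_deg prescribed fascicle angle to the long axis, in
#'   `[0, 90)` degrees
#' @param thickness_mm inter-aponeurosis distance (> 0)
#' @param origin world position of the slab corner (mm)
#' @param long_axis unit vector of the muscle long axis
#' @param normal unit vector normal to the aponeurosis planes (orthogonal
#'   to `long_axis`)
#' @param arc_radius_mm circular-arc radius; `Inf` for straight fascicles;
#'   finite values must exceed `thickness_mm`
#' @param extent_mm in-plane extents (length 2, mm)
#' @param geometry `"slab"` or `"bipennate"` (mirrored slab pair sharing the
#'   central aponeurosis plane; total thickness `2 * thickness_mm`)
#' @return object of class `myo_compartment_spec`
#' @export
compartment_spec <- function(label, pennation_deg, thickness_mm,
                             origin = c(0, 0, 0),
                             long_axis = c(0, 0, 1), normal = c(1, 0, 0),
                             arc_radius_mm = Inf,
                             extent_mm = c(50, 40),
                             geometry = c("slab", "bipennate")) {
  geometry <- match.arg(geometry)
  stopifnot(
    label >= 1, pennation_deg >= 0, pennation_deg < 90, thickness_mm > 0,
    length(extent_mm) == 2, all(extent_mm > 0)
  )
  if (is.finite(arc_radius_mm) && arc_radius_mm <= thickness_mm) {
    stop("arc_radius_mm must exceed thickness_mm")
  }
  long_axis <- unit(long_axis)
  normal <- unit(normal)
  if (abs(sum(long_axis * normal)) > 1e-8) {
    stop("normal must be orthogonal to long_axis")
  }
  structure(list(
    label = as.integer(label), geometry = geometry,
    pennation_deg = pennation_deg, thickness_mm = thickness_mm,
    origin = origin, long_axis = long_axis, normal = normal,
    arc_radius_mm = arc_radius_mm, extent_mm = extent_mm
  ), class = "myo_compartment_spec")
}

# local frame: n (aponeurosis normal), a (long axis), b = n x a,
# f (fascicle direction), m (end-cap normal, orthogonal to f and b)
compartment_frame <- function(cs) {
  n <- cs$normal
  a <- cs$long_axis
  b <- cross3(a, n)
  th <- deg2rad(cs$pennation_deg)
  f <- cos(th) * a + sin(th) * n
  m <- if (cs$pennation_deg == 0) a else unit(sin(th) * a - cos(th) * n)
  list(n = n, a = a, b = b, f = f, m = m, theta = th)
}

# centre of the concentric-arc family: for arc compartments, `origin`
# (offset by t/2 along the normal and e_b/2 laterally) anchors the mid-arc
# point, which sits at distance R from the centre along the inward radial
# of the prescribed tangent direction
arc_centre <- function(cs, fr) {
  R <- cs$arc_radius_mm
  th <- fr$theta
  mid <- cs$origin + (cs$thickness_mm / 2) * fr$n + (cs$extent_mm[2] / 2) * fr$b
  mid - R * cos(th) * fr$n + R * sin(th) * fr$a
}

# slab-coordinate membership of world points (rows); returns logical vector.
# Straight compartments are sheared slabs (end-caps parallel to the
# fascicle direction); arc compartments are annular sectors: radius within
# thickness/2 of arc_radius, angular extent extent_mm[1]/arc_radius.
compartment_contains <- function(cs, points) {
  fr <- compartment_frame(cs)
  points <- matrix(points, ncol = 3)
  rel <- sweep(points, 2, cs$origin, "-")
  v <- rel %*% fr$b
  v_ok <- v >= 0 & v < cs$extent_mm[2]
  if (!is.finite(cs$arc_radius_mm)) {
    u <- rel %*% fr$n
    w <- rel %*% fr$m
    tmax <- if (cs$geometry == "bipennate") 2 * cs$thickness_mm else cs$thickness_mm
    return(u >= 0 & u < tmax & w >= 0 & w < cs$extent_mm[1] & v_ok)
  }
  R <- cs$arc_radius_mm
  ctr <- arc_centre(cs, fr)
  relc <- sweep(points, 2, ctr, "-")
  uc <- as.vector(relc %*% fr$n)
  wc <- as.vector(relc %*% fr$a)
  rho <- sqrt(uc^2 + wc^2)
  # angular deviation from the central radial (R cos(theta), -R sin(theta))
  r0 <- c(cos(fr$theta), -sin(fr$theta))
  dot <- uc * r0[1] + wc * r0[2]
  crs <- uc * r0[2] - wc * r0[1]
  dphi <- abs(atan2(crs, dot))
  half_span <- cs$extent_mm[1] / (2 * R)
  abs(rho - R) <= cs$thickness_mm / 2 & dphi <= half_span & v_ok
}

# unit fascicle tangent at world points (rows); n x 3 matrix
compartment_tangents <- function(cs, points) {
  fr <- compartment_frame(cs)
  points <- matrix(points, ncol = 3)
  np <- nrow(points)
  if (!is.finite(cs$arc_radius_mm)) {
    f <- fr$f
    if (cs$geometry == "bipennate") {
      rel <- sweep(points, 2, cs$origin, "-")
      u <- as.vector(rel %*% fr$n)
      th <- fr$theta
      f2 <- cos(th) * fr$a - sin(th) * fr$n  # mirrored upper half
      out <- matrix(f, np, 3, byrow = TRUE)
      out[u >= cs$thickness_mm, ] <- matrix(f2, sum(u >= cs$thickness_mm), 3,
                                            byrow = TRUE)
      return(out)
    }
    return(matrix(f, np, 3, byrow = TRUE))
  }
  # concentric circular arcs in the (n, a) plane about a centre chosen so
  # the tangent at the slab's central point is the prescribed direction
  rel <- sweep(points, 2, arc_centre(cs, fr), "-")
  u <- as.vector(rel %*% fr$n)
  w <- as.vector(rel %*% fr$a)
  rho <- sqrt(u^2 + w^2)
  tang <- (-w / rho) %o% fr$n + (u / rho) %o% fr$a
  flip <- as.vector(tang %*% fr$a) < 0
  tang[flip, ] <- -tang[flip, ]
  tang
}

#' Specify a whole phantom
#'
#' @param grid_shape voxels per axis (length 3)
#' @param voxel_size mm per axis; default matches a typical muscle DTI
#'   acquisition (1.875 x 1.875 x 5 mm)
#' @param compartments list of [compartment_spec()] objects
#' @param eigenvalues diffusion eigenvalues (lambda1 >= lambda2 >= lambda3,
#'   mm^2/s); defaults give FA 0.22 and MD 1.37e-3 mm^2/s, inside the
#'   tracking windows
#' @param s0 baseline (b = 0) signal
#' @param noise_sigma Rician noise scale (0 = noiseless)
#' @param rng_seed integer seed for noise generation
#' @return object of class `myo_phantom_spec`
#' @export
phantom_spec <- function(grid_shape, voxel_size = c(1.875, 1.875, 5),
                         compartments,
                         eigenvalues = c(1.7e-3, 1.3e-3, 1.1e-3),
                         s0 = 1000, noise_sigma = 0, rng_seed = 1L) {
  stopifnot(
    length(grid_shape) == 3, all(grid_shape >= 1),
    length(voxel_size) == 3, all(voxel_size > 0),
    length(eigenvalues) == 3,
    eigenvalues[1] >= eigenvalues[2], eigenvalues[2] >= eigenvalues[3],
    eigenvalues[3] > 0,
    s0 > 0, noise_sigma >= 0
  )
  labels <- vapply(compartments, function(x) x$label, integer(1))
  if (anyDuplicated(labels)) stop("duplicate compartment labels")
  structure(list(
    grid_shape = as.integer(grid_shape), voxel_size = voxel_size,
    compartments = compartments, eigenvalues = eigenvalues,
    s0 = s0, noise_sigma = noise_sigma, rng_seed = as.integer(rng_seed)
  ), class = "myo_phantom_spec")
}

# analytic ground truth for one compartment
compartment_truth <- function(cs) {
  th <- deg2rad(cs$pennation_deg)
  t_mm <- cs$thickness_mm
  fr <- compartment_frame(cs)
  if (!is.finite(cs$arc_radius_mm)) {
    # straight slab: fascicles span the inter-aponeurosis distance
    flen <- if (cs$pennation_deg > 0) t_mm / sin(th) else NA_real_
    curv <- 0
    tmax <- if (cs$geometry == "bipennate") 2 * t_mm else t_mm
    detv <- abs(det(rbind(fr$n, fr$b, fr$m)))
    vol_mm3 <- tmax * cs$extent_mm[1] * cs$extent_mm[2] / detv
  } else {
    # annular sector: arcs of radius rho in [R - t/2, R + t/2]; with seeds
    # uniform over the sector area, E[1/rho] = 1/R exactly and E[arc
    # length] = extent * (1 + t^2/(12 R^2)) ~ extent
    flen <- cs$extent_mm[1]
    curv <- 1000 / cs$arc_radius_mm
    vol_mm3 <- t_mm * cs$extent_mm[1] * cs$extent_mm[2]
  }
  vol_cm3 <- vol_mm3 / 1000
  data.frame(
    label = cs$label,
    fascicle_length_mm = flen,
    pennation_deg = cs$pennation_deg,
    curvature_per_m = curv,
    volume_cm3 = vol_cm3,
    pcsa_cm2 = vol_cm3 / (flen / 10)
  )
}

#' Generate a phantom
#'
#' Voxelises the compartments onto the grid, assigns every in-compartment
#' voxel a diffusion tensor whose primary eigenvector is the unit tangent of
#' the prescribed fascicle trajectory through the voxel centre, extracts a
#' closed surface mesh per compartment, and returns the analytic ground
#' truth. Background voxels receive an isotropic tensor with MD
#' 3e-3 mm^2/s, outside the tracking windows by construction.
#'
#' Partial-volume voxels at compartment faces are resolved by geometric
#' majority over 8 sub-points per voxel (ties go to background, then to the
#' smaller label).
#'
#' @param spec a [phantom_spec()]
#' @return list with `tensors` (a `myo_tensor_volume`), `labels` (a
#'   `myo_label_volume`), `meshes` (named list of `myo_mesh`), `truth`
#'   (data frame, one row per compartment) and `spec`
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "myo_phantom_spec"))
  shape <- spec$grid_shape
  affine <- affine_from_spacing(spec$voxel_size)
  centres <- grid_centres(shape, affine)
  nvox <- nrow(centres)

  # overlap check on voxel centres
  inside <- vapply(spec$compartments, function(cs) {
    as.vector(compartment_contains(cs, centres))
  }, logical(nvox))
  inside <- matrix(inside, nrow = nvox)
  n_in <- rowSums(inside)
  if (any(n_in > 1)) {
    bad <- which(n_in > 1)[1]
    labs <- vapply(spec$compartments[which(inside[bad, ])],
                   function(x) x$label, integer(1))
    stop("compartments overlap in voxel space: labels ",
         paste(labs, collapse = ", "))
  }

  # 8-sub-point majority vote for voxel labels
  offs <- as.matrix(expand.grid(c(-0.25, 0.25), c(-0.25, 0.25), c(-0.25, 0.25)))
  offs <- sweep(offs, 2, spec$voxel_size, "*")
  counts <- matrix(0L, nvox, length(spec$compartments))
  for (r in seq_len(nrow(offs))) {
    pts <- sweep(centres, 2, offs[r, ], "+")
    for (ci in seq_along(spec$compartments)) {
      counts[, ci] <- counts[, ci] +
        as.integer(compartment_contains(spec$compartments[[ci]], pts))
    }
  }
  bg_count <- nrow(offs) - rowSums(counts)
  lab_vec <- integer(nvox)
  best <- apply(counts, 1, max)
  # majority of sub-points wins; an exact compartment/background tie is
  # resolved by the voxel centre (unbiased for planar faces); compartment/
  # compartment ties go to the smaller label via which.max
  centre_in <- rowSums(inside) > 0
  assign_idx <- which(best > bg_count | (best == bg_count & centre_in))
  if (length(assign_idx)) {
    pick <- apply(counts[assign_idx, , drop = FALSE], 1, which.max)
    lab_vec[assign_idx] <- vapply(spec$compartments, function(x) x$label,
                                  integer(1))[pick]
  }
  labels_arr <- array(lab_vec, dim = shape)

  # tensor field
  lam <- spec$eigenvalues
  D <- array(0, dim = c(shape, 6))  # order: xx, yy, zz, xy, xz, yz
  iso_bg <- 3e-3
  D[, , , 1] <- iso_bg
  D[, , , 2] <- iso_bg
  D[, , , 3] <- iso_bg
  Dmat <- matrix(D, nvox, 6)
  for (ci in seq_along(spec$compartments)) {
    cs <- spec$compartments[[ci]]
    vox <- which(lab_vec == cs$label)
    if (!length(vox)) next
    tang <- compartment_tangents(cs, centres[vox, , drop = FALSE])
    # D = l1 f f' + l2 u2 u2' + l3 u3 u3'; complement varies smoothly enough
    for (r in seq_along(vox)) {
      f <- tang[r, ]
      comp <- orthonormal_complement(f)
      Dm <- lam[1] * tcrossprod(f) + lam[2] * tcrossprod(comp[, 1]) +
        lam[3] * tcrossprod(comp[, 2])
      Dmat[vox[r], ] <- c(Dm[1, 1], Dm[2, 2], Dm[3, 3],
                          Dm[1, 2], Dm[1, 3], Dm[2, 3])
    }
  }
  D <- array(Dmat, dim = c(shape, 6))

  tensors <- tensor_volume(D, affine, mask = labels_arr > 0)
  labels <- label_volume(labels_arr, affine)
  meshes <- stats::setNames(
    lapply(spec$compartments, function(cs) {
      surface_from_mask(labels_arr == cs$label, affine, label = cs$label)
    }),
    vapply(spec$compartments, function(cs) as.character(cs$label), character(1))
  )
  truth <- do.call(rbind, lapply(spec$compartments, compartment_truth))
  list(tensors = tensors, labels = labels, meshes = meshes, truth = truth,
       spec = spec, affine = affine)
}

#' Synthesise diffusion-weighted volumes from a tensor field
#'
#' Noiseless signal per direction g: \eqn{S = S_0 \exp(-b g^T D g)}.
#' Rician noise (magnitude of a complex Gaussian perturbation, independent
#' per measurement) is applied when `noise_sigma > 0`.
#'
#' @param tensors a `myo_tensor_volume`
#' @param b_value diffusion weighting (s/mm^2), > 0
#' @param directions matrix of >= 6 non-coplanar unit vectors (rows)
#' @param s0 baseline signal
#' @param noise_sigma Rician noise scale in signal units
#' @param rng_seed integer seed
#' @return list with `b0` (3D array), `dwi` (4D array, one volume per
#'   direction), `bvals`, `bvecs` (including the leading b0 entry) and
#'   `affine`
#' @export
synthesize_dwi <- function(tensors, b_value = 500, directions = default_gradients(),
                           s0 = 1000, noise_sigma = 0, rng_seed = 1L) {
  stopifnot(inherits(tensors, "myo_tensor_volume"), b_value > 0)
  directions <- matrix(directions, ncol = 3)
  if (nrow(directions) < 6) stop("at least 6 gradient directions are required")
  X <- tensor_design_matrix(directions)
  if (qr(X)$rank < 6) stop("gradient directions are coplanar; tensor not recoverable")
  shape <- dim(tensors$D)[1:3]
  nvox <- prod(shape)
  Dmat <- matrix(tensors$D, nvox, 6)
  expo <- Dmat %*% t(X)            # g' D g per direction
  S <- s0 * exp(-b_value * expo)   # nvox x ndir
  b0 <- array(s0, dim = shape)
  if (noise_sigma > 0) {
    set.seed(rng_seed)
    nmeas <- length(S)
    S <- sqrt((S + stats::rnorm(nmeas, 0, noise_sigma))^2 +
                stats::rnorm(nmeas, 0, noise_sigma)^2)
    b0 <- sqrt((b0 + stats::rnorm(nvox, 0, noise_sigma))^2 +
                 stats::rnorm(nvox, 0, noise_sigma)^2)
  }
  list(
    b0 = b0,
    dwi = array(S, dim = c(shape, nrow(directions))),
    bvals = c(0, rep(b_value, nrow(directions))),
    bvecs = rbind(c(0, 0, 0), directions),
    affine = tensors$affine
  )
}

#' Four-slab soleus-like phantom preset
#'
#' Four unipennate slabs stacked along x with distinct pennations
#' (MA 28, LA 30, MP 38, LP 35 degrees), emulating the four-compartment
#' organisation of the human soleus (medial/lateral x anterior/posterior).
#' Slab thickness is 13 in-plane voxels (24.375 mm) so aponeurosis faces
#' fall exactly on voxel boundaries and ground truth is exact. Pennations
#' below ~25 degrees are not used because, with 1.875 mm voxels and the
#' 2-voxel boundary layer, the 20-mm extension filter would reject every
#' fascicle (see the methods vignette).
#'
#' @param arc_radius_mm arc radius applied to all compartments (default
#'   `Inf`, straight fascicles)
#' @param noise_sigma Rician noise scale
#' @param rng_seed integer seed
#' @return a [phantom_spec()]
#' @export
phantom_four_slab <- function(arc_radius_mm = Inf, noise_sigma = 0,
                              rng_seed = 1L) {
  vox <- c(1.875, 1.875, 5)
  thick <- 13 * vox[1]          # 24.375 mm
  gap <- 4 * vox[1]             # 7.5 mm between slabs
  penn <- c(MA = 28, LA = 30, MP = 38, LP = 35)
  x0 <- 4 * vox[1]
  comps <- vector("list", 4)
  for (i in 1:4) {
    comps[[i]] <- compartment_spec(
      label = i, pennation_deg = penn[[i]], thickness_mm = thick,
      origin = c(x0, 7.5, 20), long_axis = c(0, 0, 1), normal = c(1, 0, 0),
      arc_radius_mm = arc_radius_mm, extent_mm = c(50, 40)
    )
    x0 <- x0 + thick + gap
  }
  # grid: x spans 4 slabs + gaps + margins; z spans the sheared footprint
  nx <- ceiling((x0 + 4 * vox[1]) / vox[1])
  ny <- ceiling((40 + 2 * 7.5) / vox[2])
  zmax <- max(vapply(comps, function(cs) {
    fr <- compartment_frame(cs)
    M <- rbind(fr$n, fr$b, fr$m)
    q <- as.matrix(expand.grid(c(0, cs$thickness_mm),
                               c(0, cs$extent_mm[2]),
                               c(0, cs$extent_mm[1])))
    corners <- t(solve(M) %*% t(q)) + matrix(cs$origin, 8, 3, byrow = TRUE)
    max(corners[, 3])
  }, numeric(1)))
  nz <- ceiling((zmax + 20) / vox[3])
  phantom_spec(
    grid_shape = c(nx, ny, nz), voxel_size = vox, compartments = comps,
    noise_sigma = noise_sigma, rng_seed = rng_seed
  )
}

#' Compartment-name map for the four-slab preset
#' @return named integer vector mapping MA/LA/MP/LP to labels 1-4
#' @export
four_slab_labels <- function() c(MA = 1L, LA = 2L, MP = 3L, LP = 4L)
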