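# Fascicle reconstruction: cubic polynomial fits to fibre tracts, linear
# extrapolation to the compartment surface, plausibility filtering and
# per-fascicle architecture metrics.

#' Fit a cubic polynomial curve to a streamline
#'
#' Independent least-squares cubic per coordinate against the normalised
#' cumulative-chord-length parameter t in `[0, 1]`. The fitted arc length
#' is computed by dense sampling.
#'
#' @param streamline a `myo_streamline` or an n x 3 point matrix (n >= 4)
#' @param n_dense number of segments for dense arc-length sampling
#' @param t optional fit parameter per point in `[0, 1]`; by default the
#'   normalised cumulative chord length of the points
#' @return object of class `myo_fascicle_curve` (pre-extension): `coef`
#'   (4 x 3), `fitted_length_mm`, `t_dense`, `s_dense` (cumulative arc
#'   length table), `points` (the input points)
#' @export
fit_polynomial <- function(streamline, n_dense = 1000, t = NULL) {
  pts <- if (inherits(streamline, "myo_streamline")) streamline$points else streamline
  pts <- matrix(pts, ncol = 3)
  if (nrow(pts) < 4) stop("at least 4 points are required for a cubic fit")
  if (is.null(t)) {
    seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
    s <- c(0, cumsum(seg))
    if (s[length(s)] < 1e-12) stop("degenerate streamline: zero total chord length")
    tt <- s / s[length(s)]
  } else {
    stopifnot(length(t) == nrow(pts))
    tt <- t
  }
  X <- cbind(1, tt, tt^2, tt^3)
  coef <- qr.solve(X, pts)  # 4 x 3
  t_dense <- seq(0, 1, length.out = n_dense + 1)
  pd <- poly_eval(coef, t_dense)
  seg_d <- sqrt(rowSums((pd[-1, , drop = FALSE] - pd[-nrow(pd), , drop = FALSE])^2))
  s_dense <- c(0, cumsum(seg_d))
  structure(list(
    coef = coef,
    fitted_length_mm = s_dense[length(s_dense)],
    t_dense = t_dense,
    s_dense = s_dense,
    points = pts,
    extensions = NULL
  ), class = "myo_fascicle_curve")
}

poly_eval <- function(coef, t) {
  cbind(1, t, t^2, t^3) %*% coef
}

poly_deriv1 <- function(coef, t) {
  cbind(0, 1, 2 * t, 3 * t^2) %*% coef
}

poly_deriv2 <- function(coef, t) {
  cbind(0, 0, 2, 6 * t) %*% coef
}

#' Extrapolate a fitted curve to the compartment surface
#'
#' Extends the curve linearly from each endpoint along the outward endpoint
#' tangent until the extension intersects the surface mesh (nearest
#' positive ray-triangle intersection). Endpoints must lie inside the mesh.
#'
#' @param curve a [fit_polynomial()] result
#' @param mesh a closed `myo_mesh`
#' @return the curve with `extensions`: per end (`start` = t 0, `end` =
#'   t 1) a list with `point` (curve endpoint), `direction` (unit outward
#'   tangent), `length_mm`, `hit` (logical) and `surface_point`; plus
#'   `extension_total_mm`, `both_hit`, `origin` and `insertion`
#'   attachment points
#' @export
extrapolate_to_surface <- function(curve, mesh) {
  stopifnot(inherits(curve, "myo_fascicle_curve"))
  p0 <- as.vector(poly_eval(curve$coef, 0))
  p1 <- as.vector(poly_eval(curve$coef, 1))
  d0 <- -unit(as.vector(poly_deriv1(curve$coef, 0)))
  d1 <- unit(as.vector(poly_deriv1(curve$coef, 1)))
  if (!point_in_mesh(p0, mesh) || !point_in_mesh(p1, mesh)) {
    stop("curve endpoint lies outside the surface mesh (upstream masking violated)")
  }
  mk <- function(p, d) {
    hit <- ray_mesh_intersection(p, d, mesh)
    list(point = p, direction = d,
         length_mm = if (hit$hit) hit$t else NA_real_,
         hit = hit$hit,
         surface_point = hit$point)
  }
  ext0 <- mk(p0, d0)
  ext1 <- mk(p1, d1)
  curve$extensions <- list(start = ext0, end = ext1)
  curve$both_hit <- ext0$hit && ext1$hit
  curve$extension_total_mm <- (if (ext0$hit) ext0$length_mm else 0) +
    (if (ext1$hit) ext1$length_mm else 0)
  curve$origin <- ext0$surface_point
  curve$insertion <- ext1$surface_point
  curve
}

#' Total fascicle length
#'
#' Sum of the dense-sampled polynomial arc length and both extension
#' lengths.
#'
#' @param curve an extrapolated `myo_fascicle_curve`
#' @return length in mm
#' @export
fascicle_length <- function(curve) {
  stopifnot(inherits(curve, "myo_fascicle_curve"), !is.null(curve$extensions))
  curve$fitted_length_mm + curve$extension_total_mm
}

#' Fascicle plausibility filter
#'
#' A fascicle is accepted when both extensions hit the surface, the total
#' extension is less than `max_extension_mm`, and the extension is less
#' than `max_extension_fraction` of the total fascicle length
#' (fit + extensions). Both bounds are strict.
#'
#' @param curve an extrapolated `myo_fascicle_curve`
#' @param max_extension_mm absolute extension bound (default 20 mm)
#' @param max_extension_fraction relative extension bound (default 0.5)
#' @return list with `accepted` (logical) and `reason` (`"ok"`,
#'   `"no_surface_hit"`, `"extension_too_long"` or
#'   `"extension_fraction_too_large"`)
#' @export
accept_fascicle <- function(curve, max_extension_mm = 20,
                            max_extension_fraction = 0.5) {
  stopifnot(inherits(curve, "myo_fascicle_curve"), !is.null(curve$extensions))
  if (!isTRUE(curve$both_hit)) {
    return(list(accepted = FALSE, reason = "no_surface_hit"))
  }
  total <- fascicle_length(curve)
  ext <- curve$extension_total_mm
  if (!(ext < max_extension_mm)) {
    return(list(accepted = FALSE, reason = "extension_too_long"))
  }
  if (!(ext / total < max_extension_fraction)) {
    return(list(accepted = FALSE, reason = "extension_fraction_too_large"))
  }
  list(accepted = TRUE, reason = "ok")
}

#' 3D pennation angle
#'
#' Acute angle between the fascicle's origin-insertion chord and the
#' muscle long axis, in degrees (range `[0, 90]`).
#'
#' @param curve an extrapolated `myo_fascicle_curve` with both surface
#'   hits, or a list with `origin` and `insertion` points
#' @param axis a [long_axis()]
#' @return angle in degrees
#' @export
pennation_angle <- function(curve, axis) {
  stopifnot(inherits(axis, "myo_long_axis"))
  chord <- curve$insertion - curve$origin
  n <- vnorm(chord)
  if (!is.finite(n) || n < 1e-9) stop("zero-length origin-insertion chord")
  rad2deg(acos(pmin(1, abs(sum(chord / n * axis$direction)))))
}

#' Mean Frenet-Serret curvature of the fitted curve
#'
#' \eqn{\kappa(t) = |r' \times r''| / |r'|^3} evaluated at `n_points`
#' points equidistant in arc length along the fitted polynomial
#' (extensions excluded), averaged and converted 1/mm to 1/m. Points with
#' a degenerate first derivative are skipped.
#'
#' @param curve a `myo_fascicle_curve`
#' @param n_points number of evaluation points (default 100)
#' @param include_extensions also average over the straight extensions
#'   (curvature 0), diluting the estimate; off by default
#' @return mean curvature in 1/m
#' @export
mean_curvature <- function(curve, n_points = 100, include_extensions = FALSE) {
  stopifnot(inherits(curve, "myo_fascicle_curve"))
  # invert the cumulative arc-length table for equidistant-in-s parameters
  s_targets <- seq(0, curve$s_dense[length(curve$s_dense)],
                   length.out = n_points)
  tt <- stats::approx(curve$s_dense, curve$t_dense, xout = s_targets,
                      ties = "ordered")$y
  r1 <- poly_deriv1(curve$coef, tt)
  r2 <- poly_deriv2(curve$coef, tt)
  cr <- cbind(
    r1[, 2] * r2[, 3] - r1[, 3] * r2[, 2],
    r1[, 3] * r2[, 1] - r1[, 1] * r2[, 3],
    r1[, 1] * r2[, 2] - r1[, 2] * r2[, 1]
  )
  speed <- sqrt(rowSums(r1^2))
  okv <- speed > 1e-12
  kappa <- sqrt(rowSums(cr^2))[okv] / speed[okv]^3
  if (include_extensions && !is.null(curve$extensions)) {
    # extensions are straight: weight zeros in by extension arc length
    w_fit <- curve$fitted_length_mm
    w_ext <- curve$extension_total_mm
    return(1000 * mean(kappa) * w_fit / (w_fit + w_ext))
  }
  1000 * mean(kappa)
}

#' Physiological cross-sectional area
#'
#' Muscle volume divided by mean fascicle length, in consistent units
#' (cm^3 / cm).
#'
#' @param volume_cm3 compartment volume (cm^3)
#' @param mean_fascicle_length_mm mean fascicle length (mm)
#' @return PCSA in cm^2
#' @export
pcsa <- function(volume_cm3, mean_fascicle_length_mm) {
  if (volume_cm3 <= 0 || mean_fascicle_length_mm <= 0) {
    stop("volume and fascicle length must be positive")
  }
  volume_cm3 / (mean_fascicle_length_mm / 10)
}

#' Fascicle length as a fraction of muscle length
#'
#' @param mean_fascicle_length_mm mean fascicle length (mm)
#' @param muscle_length_mm whole-muscle length (mm)
#' @return dimensionless ratio
#' @export
normalized_fascicle_length <- function(mean_fascicle_length_mm,
                                       muscle_length_mm) {
  stopifnot(mean_fascicle_length_mm > 0, muscle_length_mm > 0)
  mean_fascicle_length_mm / muscle_length_mm
}

#' Length and pennation of a digitised fascicle polyline
#'
#' For cadaver-dissection digitisations: fascicle length is the summed
#' segment length of the polyline; pennation is the acute angle between
#' the first-to-last chord and a reference line (two points on the
#' anterior surface of the medial septum). Duplicate consecutive points
#' are collapsed (and counted).
#'
#' @param points n x 3 matrix of digitised points (mm), n >= 2
#' @param ref_p1,ref_p2 two distinct points defining the reference line
#' @return list with `length_mm`, `pennation_deg` and
#'   `n_duplicates_collapsed`
#' @export
digitised_polyline_metrics <- function(points, ref_p1, ref_p2) {
  points <- matrix(points, ncol = 3)
  if (nrow(points) < 2) stop("at least 2 points are required")
  if (vnorm(ref_p2 - ref_p1) < 1e-9) stop("reference points must be distinct")
  keep <- c(TRUE, rowSums((points[-1, , drop = FALSE] -
                             points[-nrow(points), , drop = FALSE])^2) > 1e-18)
  n_dup <- sum(!keep)
  points <- points[keep, , drop = FALSE]
  if (nrow(points) < 2) stop("fewer than 2 distinct points after collapsing duplicates")
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                         points[-nrow(points), , drop = FALSE])^2))
  chord <- unit(points[nrow(points), ] - points[1, ])
  refdir <- unit(ref_p2 - ref_p1)
  list(
    length_mm = sum(seg),
    pennation_deg = rad2deg(acos(pmin(1, abs(sum(chord * refdir))))),
    n_duplicates_collapsed = n_dup
  )
}

#' Reconstruct fascicles for one compartment
#'
#' Runs fit, extrapolation, filtering and metrics for a list of
#' streamlines against the compartment surface, returning the per-fascicle
#' table.
#'
#' @param streamlines list of `myo_streamline` (from [track_compartment()])
#' @param mesh the compartment `myo_mesh`
#' @param axis a [long_axis()]
#' @param compartment compartment name recorded in the table
#' @param max_extension_mm,max_extension_fraction filter thresholds
#' @return data frame with one row per input streamline: `id`,
#'   `compartment`, `length_mm`, `pennation_deg`, `curvature_per_m`,
#'   `extension_mm`, `extension_fraction`, `accepted`, `reason`
#' @export
reconstruct_fascicles <- function(streamlines, mesh, axis,
                                  compartment = NA_character_,
                                  max_extension_mm = 20,
                                  max_extension_fraction = 0.5) {
  rows <- lapply(seq_along(streamlines), function(i) {
    curve <- extrapolate_to_surface(fit_polynomial(streamlines[[i]]), mesh)
    acc <- accept_fascicle(curve, max_extension_mm, max_extension_fraction)
    len <- if (curve$both_hit) fascicle_length(curve) else NA_real_
    penn <- if (curve$both_hit) pennation_angle(curve, axis) else NA_real_
    data.frame(
      id = i, compartment = compartment,
      length_mm = len, pennation_deg = penn,
      curvature_per_m = mean_curvature(curve),
      extension_mm = if (curve$both_hit) curve$extension_total_mm else NA_real_,
      extension_fraction = if (curve$both_hit) curve$extension_total_mm / len
        else NA_real_,
      accepted = acc$accepted, reason = acc$reason,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
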