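# Deterministic streamline tractography through the primary-eigenvector
# field, with FA/MD acceptance windows, per-step angle threshold and
# boundary-layer termination.

#' Tracking parameters
#'
#' Defaults follow established muscle-DTI settings: FA window `[0.1, 0.5]`,
#' MD window `[1e-3, 2e-3]` mm^2/s, maximum inter-segment angle 10 degrees,
#' 1 mm steps, accepted tract length 15-200 mm, 1000 tracts per
#' compartment.
#'
#' @param fa_min,fa_max fractional-anisotropy window
#' @param md_min,md_max mean-diffusivity window (mm^2/s)
#' @param max_angle_deg maximum angle between subsequent tract segments
#'   (degrees); ties at exactly this angle are accepted
#' @param step_mm step size (mm)
#' @param min_length_mm,max_length_mm accepted tract length window (mm)
#' @param n_target number of accepted tracts to collect per compartment
#' @param max_seed_attempts seeding budget (default `100 * n_target`)
#' @param interp `"trilinear"` or `"nearest"` sampling of e1/FA/MD
#' @param rng_seed integer seed for seed-point sampling
#' @return object of class `myo_tracking_params`
#' @export
tracking_params <- function(fa_min = 0.1, fa_max = 0.5,
                            md_min = 1e-3, md_max = 2e-3,
                            max_angle_deg = 10, step_mm = 1,
                            min_length_mm = 15, max_length_mm = 200,
                            n_target = 1000,
                            max_seed_attempts = 100 * n_target,
                            interp = c("trilinear", "nearest"),
                            rng_seed = 1L) {
  interp <- match.arg(interp)
  stopifnot(
    fa_min >= 0, fa_min < fa_max, fa_max <= 1,
    md_min < md_max, step_mm > 0,
    min_length_mm < max_length_mm, n_target >= 1, max_seed_attempts >= 1
  )
  structure(list(
    fa_min = fa_min, fa_max = fa_max, md_min = md_min, md_max = md_max,
    max_angle_deg = max_angle_deg, step_mm = step_mm,
    min_length_mm = min_length_mm, max_length_mm = max_length_mm,
    n_target = as.integer(n_target),
    max_seed_attempts = as.integer(max_seed_attempts),
    interp = interp, rng_seed = as.integer(rng_seed)
  ), class = "myo_tracking_params")
}

# Sample e1 (sign-aligned to ref), FA and MD at a world point.
# Returns NULL when the interpolation neighbourhood leaves the grid.
sample_field <- function(em, inv_affine, point, ref, interp) {
  ci <- as.vector(inv_affine[1:3, 1:3] %*% point + inv_affine[1:3, 4])
  d <- dim(em$fa)
  if (interp == "nearest") {
    v <- floor(ci + 0.5) + 1
    if (any(v < 1) || any(v > d)) return(NULL)
    e1 <- em$e1[v[1], v[2], v[3], ]
    if (!is.null(ref) && sum(e1 * ref) < 0) e1 <- -e1
    return(list(e1 = e1, fa = em$fa[v[1], v[2], v[3]],
                md = em$md[v[1], v[2], v[3]]))
  }
  i0 <- floor(ci)
  f <- ci - i0
  i0 <- i0 + 1
  if (any(i0 < 1) || any(i0 + 1 > d)) return(NULL)
  ii <- c(i0[1], i0[1] + 1)[c(1, 2, 1, 2, 1, 2, 1, 2)]
  jj <- c(i0[2], i0[2] + 1)[c(1, 1, 2, 2, 1, 1, 2, 2)]
  kk <- c(i0[3], i0[3] + 1)[c(1, 1, 1, 1, 2, 2, 2, 2)]
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
  idx <- cbind(ii, jj, kk)
  fa <- sum(w * em$fa[idx])
  md <- sum(w * em$md[idx])
  ev <- cbind(em$e1[cbind(idx, 1)], em$e1[cbind(idx, 2)], em$e1[cbind(idx, 3)])
  # per-lobe sign alignment: flip corner vectors opposing the reference
  r <- if (is.null(ref)) ev[1, ] else ref
  flip <- as.vector(ev %*% r) < 0
  ev[flip, ] <- -ev[flip, ]
  e1 <- as.vector(w %*% ev)
  n <- vnorm(e1)
  if (!is.finite(n) || n < 1e-12) return(list(e1 = NULL, fa = fa, md = md))
  list(e1 = e1 / n, fa = fa, md = md)
}

# voxel (1-based) containing a world point, or NULL if off-grid
point_voxel <- function(inv_affine, point, d) {
  ci <- as.vector(inv_affine[1:3, 1:3] %*% point + inv_affine[1:3, 4])
  v <- floor(ci + 0.5) + 1
  if (any(v < 1) || any(v > d)) return(NULL)
  v
}

#' Track a single streamline from a seed point
#'
#' Grows two half-tracks from the seed along +e1 and -e1. Each step samples
#' e1 at the current point (sign-aligned to the previous direction),
#' rejects the step if the inter-segment angle exceeds the threshold, and
#' accepts the candidate point only while it stays inside the compartment
#' mask, outside the boundary layer, and inside the FA/MD windows
#' (evaluated at the candidate point). No partial steps are taken: the
#' last accepted point is the endpoint.
#'
#' @param seed world seed point (mm)
#' @param em a [eigen_maps()] result
#' @param masks list with logical arrays `compartment` and `boundary`
#'   (DTI grid)
#' @param params a [tracking_params()]
#' @return a `myo_streamline` (list with `points`, `seed`,
#'   `termination`, `length_mm`, `accepted`, `reject_reason`) or, on seed
#'   rejection, a list with `accepted = FALSE` and `reject_reason`
#' @export
track_from_seed <- function(seed, em, masks, params = tracking_params()) {
  inv_affine <- solve(em$affine)
  d <- dim(em$fa)
  v <- point_voxel(inv_affine, seed, d)
  if (is.null(v) || !masks$compartment[v[1], v[2], v[3]]) {
    return(list(accepted = FALSE, reject_reason = "seed_outside_mask"))
  }
  s0 <- sample_field(em, inv_affine, seed, NULL, params$interp)
  if (is.null(s0) || is.null(s0$e1) || !is.finite(s0$fa) || !is.finite(s0$md)) {
    return(list(accepted = FALSE, reject_reason = "nonfinite_field"))
  }
  if (s0$fa < params$fa_min || s0$fa > params$fa_max) {
    return(list(accepted = FALSE, reject_reason = "seed_fa_window"))
  }
  if (s0$md < params$md_min || s0$md > params$md_max) {
    return(list(accepted = FALSE, reject_reason = "seed_md_window"))
  }
  max_steps_total <- floor(params$max_length_mm / params$step_mm)
  cos_tol <- cos(deg2rad(params$max_angle_deg)) - 1e-12

  grow_half <- function(dir0, max_steps) {
    pts <- matrix(seed, 1, 3)
    prev <- dir0
    cur <- seed
    reason <- "max_length"
    while (nrow(pts) - 1 < max_steps) {
      s <- sample_field(em, inv_affine, cur, prev, params$interp)
      if (is.null(s)) { reason <- "out_of_volume"; break }
      if (is.null(s$e1) || !is.finite(s$fa) || !is.finite(s$md)) {
        reason <- "nonfinite_field"; break
      }
      dirn <- s$e1
      if (sum(dirn * prev) < cos_tol) { reason <- "angle"; break }
      cand <- cur + params$step_mm * dirn
      vv <- point_voxel(inv_affine, cand, d)
      if (is.null(vv)) { reason <- "out_of_volume"; break }
      if (!masks$compartment[vv[1], vv[2], vv[3]]) { reason <- "out_of_volume"; break }
      if (masks$boundary[vv[1], vv[2], vv[3]]) { reason <- "boundary"; break }
      sc <- sample_field(em, inv_affine, cand, dirn, params$interp)
      if (is.null(sc) || !is.finite(sc$fa) || !is.finite(sc$md)) {
        reason <- "nonfinite_field"; break
      }
      if (sc$fa < params$fa_min || sc$fa > params$fa_max) { reason <- "fa_window"; break }
      if (sc$md < params$md_min || sc$md > params$md_max) { reason <- "md_window"; break }
      pts <- rbind(pts, cand)
      cur <- cand
      prev <- dirn
    }
    list(points = pts, reason = reason)
  }

  hp <- grow_half(s0$e1, max_steps_total)
  hm <- grow_half(-s0$e1, max_steps_total - (nrow(hp$points) - 1))
  npts_m <- nrow(hm$points)
  pts <- rbind(
    hm$points[rev(seq_len(npts_m))[-npts_m], , drop = FALSE],
    hp$points
  )
  len <- params$step_mm * (nrow(pts) - 1)
  accepted <- len >= params$min_length_mm && len <= params$max_length_mm
  structure(list(
    points = unname(pts),
    seed = seed,
    termination = c(start = hm$reason, end = hp$reason),
    length_mm = len,
    accepted = accepted,
    reject_reason = if (accepted) NA_character_ else
      if (len < params$min_length_mm) "too_short" else "too_long"
  ), class = "myo_streamline")
}

#' Track a compartment
#'
#' Draws seeds uniformly at random (voxel chosen uniformly from the seed
#' mask, position jittered uniformly within the voxel) until `n_target`
#' accepted streamlines are collected or the seeding budget is exhausted,
#' in which case a warning is issued and the partial result returned.
#' Fully reproducible for a given `rng_seed`.
#'
#' @param em a [eigen_maps()] result
#' @param masks list with logical arrays `compartment`, `seed`, `boundary`
#' @param params a [tracking_params()]
#' @param rng_seed seed for this compartment (default `params$rng_seed`)
#' @return list of accepted `myo_streamline`s; attributes `n_attempts`,
#'   `acceptance_rate` and `rejections` (named table of rejection reasons)
#' @export
track_compartment <- function(em, masks, params = tracking_params(),
                              rng_seed = params$rng_seed) {
  if (!any(masks$seed)) stop("seed mask is empty")
  seed_idx <- which(masks$seed, arr.ind = TRUE) - 1L  # 0-based centres
  n_seed_vox <- nrow(seed_idx)
  set.seed(rng_seed)
  accepted <- vector("list", params$n_target)
  n_acc <- 0L
  n_att <- 0L
  rejections <- c()
  while (n_acc < params$n_target && n_att < params$max_seed_attempts) {
    n_att <- n_att + 1L
    vox <- seed_idx[sample.int(n_seed_vox, 1L), ]
    jitter <- stats::runif(3) - 0.5
    seed <- as.vector(voxel_to_world(em$affine, vox + jitter))
    sl <- track_from_seed(seed, em, masks, params)
    if (isTRUE(sl$accepted)) {
      n_acc <- n_acc + 1L
      accepted[[n_acc]] <- sl
    } else {
      r <- sl$reject_reason
      rejections[r] <- (if (r %in% names(rejections)) rejections[[r]] else 0L) + 1L
    }
  }
  accepted <- accepted[seq_len(n_acc)]
  if (n_acc < params$n_target) {
    warning(sprintf(
      "seeding budget exhausted: %d of %d tracts accepted after %d attempts (sparse fibre tracts)",
      n_acc, params$n_target, n_att
    ))
  }
  attr(accepted, "n_attempts") <- n_att
  attr(accepted, "acceptance_rate") <- n_acc / n_att
  attr(accepted, "rejections") <- rejections
  accepted
}
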