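# Shared fixtures, built in code and memoised across tests within a run.

unit <- function(v) v / sqrt(sum(v^2))

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small single-slab phantom (straight fascicles, 30 deg) on the standard
# anisotropic grid; big enough for seeds, small enough to be fast
small_slab_phantom <- function() {
  memo("small_slab", {
    cs <- compartment_spec(
      label = 1L, pennation_deg = 30, thickness_mm = 13 * 1.875,
      origin = c(7.5, 7.5, 20), extent_mm = c(40, 40)
    )
    spec <- phantom_spec(grid_shape = c(28, 30, 28), compartments = list(cs),
                         rng_seed = 5L)
    c(generate_phantom(spec), list(spec = spec))
  })
}

small_slab_eigen <- function() {
  memo("small_slab_em", eigen_maps(small_slab_phantom()$tensors))
}

small_slab_masks <- function() {
  memo("small_slab_masks", {
    ph <- small_slab_phantom()
    make_seed_and_boundary_masks(ph$labels, ph$affine, dim(ph$labels$data))
  })
}

# arc phantom: annular sector in the fine-voxel (x, y) plane, R = 58.8 mm
arc_phantom <- function() {
  memo("arc_phantom", {
    cs <- compartment_spec(
      label = 1L, pennation_deg = 40, thickness_mm = 25,
      origin = c(30, 75, 25), arc_radius_mm = 58.8,
      long_axis = c(0, 1, 0), normal = c(1, 0, 0), extent_mm = c(45, 40)
    )
    spec <- phantom_spec(grid_shape = c(40, 64, 18), compartments = list(cs),
                         rng_seed = 7L)
    c(generate_phantom(spec), list(spec = spec))
  })
}

arc_axis <- function() long_axis(c(30, 150, 25), c(30, 10, 25))

slab_axis <- function() long_axis(c(30, 27, 150), c(30, 27, 10))

# synthetic eigen-maps object with a prescribed unit direction field and
# in-window FA/MD, for tracking tests that need analytic fields
synthetic_eigenmaps <- function(shape, dir_fun, affine = diag(4),
                                fa = 0.3, md = 1.5e-3) {
  e1 <- array(0, c(shape, 3))
  centres <- myotract:::grid_centres(shape, affine)
  dirs <- t(apply(centres, 1, dir_fun))
  for (k in 1:3) e1[, , , k] <- array(dirs[, k], shape)
  structure(list(
    lambda1 = array(2e-3, shape), lambda2 = array(1.3e-3, shape),
    lambda3 = array(1.2e-3, shape),
    e1 = e1, e2 = array(0, c(shape, 3)), e3 = array(0, c(shape, 3)),
    fa = array(fa, shape), md = array(md, shape),
    mask = array(TRUE, shape), affine = affine,
    n_clamped = 0L, n_dropped = 0L
  ), class = "myo_eigen_maps")
}

# minimal extended-curve stub for filter-semantics tests
stub_curve <- function(fitted_length_mm, ext_start_mm, ext_end_mm,
                       hit_start = TRUE, hit_end = TRUE) {
  ext <- function(len, hit) {
    list(point = c(0, 0, 0), direction = c(0, 0, 1),
         length_mm = if (hit) len else NA_real_, hit = hit,
         surface_point = if (hit) c(0, 0, len) else rep(NA_real_, 3))
  }
  structure(list(
    coef = rbind(c(0, 0, 0), c(0, 0, fitted_length_mm), 0, 0),
    fitted_length_mm = fitted_length_mm,
    t_dense = seq(0, 1, length.out = 11),
    s_dense = seq(0, fitted_length_mm, length.out = 11),
    extensions = list(start = ext(ext_start_mm, hit_start),
                      end = ext(ext_end_mm, hit_end)),
    both_hit = hit_start && hit_end,
    extension_total_mm = (if (hit_start) ext_start_mm else 0) +
      (if (hit_end) ext_end_mm else 0),
    origin = c(0, 0, -ext_start_mm),
    insertion = c(0, 0, fitted_length_mm + ext_end_mm)
  ), class = "myo_fascicle_curve")
}

# three-point circumcircle curvature of a discrete curve (1/mm)
discrete_curvature <- function(pts) {
  n <- nrow(pts)
  k <- numeric(n - 2)
  for (i in 2:(n - 1)) {
    a <- pts[i - 1, ]; b <- pts[i, ]; c_ <- pts[i + 1, ]
    la <- sqrt(sum((b - a)^2)); lb <- sqrt(sum((c_ - b)^2))
    lc <- sqrt(sum((c_ - a)^2))
    s <- (la + lb + lc) / 2
    area <- sqrt(max(0, s * (s - la) * (s - lb) * (s - lc)))
    k[i - 1] <- 4 * area / (la * lb * lc)
  }
  k
}

# simulate a balanced random-intercept cohort
simulate_cohort <- function(n_subjects, beta, sigma_subject, sigma_e,
                            conditions = "short", beta_long = NULL) {
  comps <- names(beta)
  rows <- list()
  for (s in seq_len(n_subjects)) {
    b_s <- stats::rnorm(1, 0, sigma_subject)
    for (comp in comps) {
      for (cond in conditions) {
        mu <- beta[[comp]] + if (cond == "long") beta_long[[comp]] else 0
        rows[[length(rows) + 1]] <- data.frame(
          subject_id = paste0("S", s), compartment = comp, condition = cond,
          value = mu + b_s + stats::rnorm(1, 0, sigma_e)
        )
      }
    }
  }
  do.call(rbind, rows)
}
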