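# polynomial fitting, surface extrapolation, filters and fascicle metrics

box_mesh <- function(nx, ny, nz, voxel = c(1, 1, 1)) {
  surface_from_mask(array(TRUE, c(nx, ny, nz)), affine_from_spacing(voxel))
}

test_that("fit_polynomial requires 4 points and handles collinear input", {
  expect_error(fit_polynomial(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))),
               "4 points")
  pts <- cbind(0, 0, seq(0, 20, by = 1))
  cv <- fit_polynomial(pts)
  expect_equal(cv$fitted_length_mm, 20, tolerance = 1e-9)
  expect_lt(mean_curvature(cv), 1e-6)
})

test_that("points sampled exactly from a cubic are reproduced to 1e-9", {
  coef <- rbind(c(0, 0, 0), c(30, 4, 25), c(-4, 3, 5), c(2, -2, 1))
  tt <- sort(c(0, stats::runif(23), 1))
  pts <- cbind(1, tt, tt^2, tt^3) %*% coef
  # fit against the generating parameterisation: polynomial identity
  cv <- fit_polynomial(pts, t = tt)
  resid <- cbind(1, tt, tt^2, tt^3) %*% cv$coef - pts
  expect_lt(max(abs(resid)), 1e-9)
  # the default chord-length parameterisation reproduces the shape (not
  # the parameterisation), so arc length agrees closely
  cv2 <- fit_polynomial(pts)
  expect_equal(cv2$fitted_length_mm, cv$fitted_length_mm, tolerance = 1e-3)
})

test_that("a noisy arc recovers its curvature within 5%", {
  set.seed(11)
  R <- 50
  phi <- seq(-0.4, 0.4, length.out = 41)  # 40 mm arc
  pts <- cbind(R * sin(phi), 0, R * (1 - cos(phi)))
  noisy <- pts + matrix(stats::rnorm(length(pts), 0, 0.2), ncol = 3)
  cv <- fit_polynomial(noisy)
  expect_equal(mean_curvature(cv), 1000 / R, tolerance = 0.05)
})

test_that("mean curvature matches 1000/R on exact arcs within 2%", {
  for (R in c(58.8, 100)) {
    phi <- seq(-20 / R, 20 / R, length.out = 41)  # 40 mm arc
    pts <- cbind(R * sin(phi), 0, R * (1 - cos(phi)))
    cv <- fit_polynomial(pts)
    expect_equal(mean_curvature(cv), 1000 / R, tolerance = 0.02)
  }
})

test_that("Frenet-Serret curvature agrees with the circumcircle oracle within 2%", {
  R <- 58.8
  phi <- seq(-0.35, 0.35, length.out = 41)
  pts <- cbind(R * sin(phi), 0.02 * R * phi^2, R * (1 - cos(phi)))
  cv <- fit_polynomial(pts)
  # oracle: three-point circumcircle curvature on dense samples of the
  # same fitted polynomial
  tt <- seq(0, 1, length.out = 400)
  dense <- cbind(1, tt, tt^2, tt^3) %*% cv$coef
  oracle <- mean(discrete_curvature(dense)) * 1000
  expect_equal(mean_curvature(cv), oracle, tolerance = 0.02)
})

test_that("extrapolation solves the ray-plane closed forms to 1e-6 mm", {
  mesh <- box_mesh(10, 10, 30)  # box [0,10] x [0,10] x [0,30]
  pts <- cbind(5, 5, seq(5, 25, length.out = 21))
  cv <- extrapolate_to_surface(fit_polynomial(pts), mesh)
  expect_true(cv$both_hit)
  expect_equal(cv$extensions$start$length_mm, 5, tolerance = 1e-6)
  expect_equal(cv$extensions$end$length_mm, 5, tolerance = 1e-6)
  expect_equal(fascicle_length(cv), 30, tolerance = 1e-6)
  expect_equal(cv$origin, c(5, 5, 0), tolerance = 1e-6)
  expect_equal(cv$insertion, c(5, 5, 30), tolerance = 1e-6)

  # 30 deg to the slab normal (x): 20 mm track inside a 20-mm-thick slab
  slab <- box_mesh(20, 40, 40)
  d <- c(sin(pi / 6), 0, cos(pi / 6))
  mid <- c(10, 20, 20)
  tt <- seq(-10, 10, length.out = 21)
  pts2 <- sweep(outer(tt, d), 2, mid, "+")
  cv2 <- extrapolate_to_surface(fit_polynomial(pts2), slab)
  expect_true(cv2$both_hit)
  expect_equal(fascicle_length(cv2), 20 / sin(pi / 6), tolerance = 1e-6)

  # tangent parallel to the slab faces: the ray exits through an end face,
  # far away; with a doubly-open geometry it must be flagged as a no-hit
  open_slab <- surface_mesh(slab$vertices, slab$faces)
  keep <- rep(TRUE, nrow(slab$faces))
  # remove faces on x = 0 and x = 20 planes to make the ray escape
  vx <- slab$vertices[, 1]
  fx <- matrix(vx[slab$faces], ncol = 3)
  keep[rowSums(fx == 0) == 3 | rowSums(fx == 20) == 3] <- FALSE
  pts3 <- cbind(seq(5, 15, length.out = 11), 20, 20)
  cv3 <- fit_polynomial(pts3)
  hit <- ray_mesh_intersection(c(15, 20, 20), c(1, 0, 0),
                               surface_mesh(slab$vertices,
                                            slab$faces[keep, , drop = FALSE]))
  expect_false(hit$hit)
})

test_that("endpoints outside the mesh raise an upstream-masking error", {
  mesh <- box_mesh(10, 10, 10)
  pts <- cbind(5, 5, seq(8, 20, length.out = 13))  # runs out the top
  expect_error(extrapolate_to_surface(fit_polynomial(pts), mesh),
               "outside the surface mesh")
})

test_that("the plausibility filter enforces both bounds strictly", {
  # 25 mm total extension -> rejected on the absolute bound
  expect_false(accept_fascicle(stub_curve(60, 12.5, 12.5))$accepted)
  # 12 mm extension on 40 mm total -> accepted (fraction 0.3)
  a <- accept_fascicle(stub_curve(28, 6, 6))
  expect_true(a$accepted)
  # 19 mm extension on 36 mm total -> fraction 0.528 -> rejected
  r <- accept_fascicle(stub_curve(17, 9.5, 9.5))
  expect_false(r$accepted)
  expect_equal(r$reason, "extension_fraction_too_large")
  # boundary cases: exactly 20 mm and exactly 0.5 are rejected (<, not <=)
  expect_false(accept_fascicle(stub_curve(60, 10, 10))$accepted)
  expect_false(accept_fascicle(stub_curve(15, 7.5, 7.5))$accepted)
  # a missing surface hit always rejects
  expect_false(accept_fascicle(stub_curve(60, 5, 5, hit_end = FALSE))$accepted)
})

test_that("the filter is monotone in extension length", {
  set.seed(13)
  for (i in 1:20) {
    fit_len <- stats::runif(1, 10, 60)
    e1 <- stats::runif(1, 0, 15)
    e2 <- stats::runif(1, 0, 15)
    extra <- stats::runif(1, 0.5, 10)
    acc_small <- accept_fascicle(stub_curve(fit_len, e1, e2))$accepted
    acc_large <- accept_fascicle(stub_curve(fit_len, e1 + extra, e2))$accepted
    expect_false(!acc_small && acc_large)
  }
})

test_that("pennation is the acute chord-axis angle", {
  axis <- long_axis(c(0, 0, 10), c(0, 0, 0))
  expect_equal(pennation_angle(list(origin = c(0, 0, 0),
                                    insertion = c(0, 0, 30)), axis), 0)
  expect_equal(pennation_angle(list(origin = c(0, 0, 0),
                                    insertion = c(1, 0, 1)), axis), 45)
  # antiparallel chords give the same acute angle
  expect_equal(pennation_angle(list(origin = c(1, 0, 1),
                                    insertion = c(0, 0, 0)), axis), 45)
  expect_error(pennation_angle(list(origin = c(1, 1, 1),
                                    insertion = c(1, 1, 1)), axis),
               "zero-length")
})

test_that("pcsa and normalised fascicle length apply unit conversions", {
  expect_equal(pcsa(40, 40), 10)
  expect_equal(pcsa(33.5, 33.5), 10)
  expect_error(pcsa(-1, 10))
  expect_error(pcsa(10, 0))
  expect_equal(normalized_fascicle_length(40, 400), 0.1)
  expect_equal(normalized_fascicle_length(123, 123), 1)
})

test_that("digitised polyline metrics match hand-computed values", {
  pts <- rbind(c(0, 0, 0), c(0, 0, 1), c(0, 0, 2))
  m <- digitised_polyline_metrics(pts, c(0, 0, 0), c(0, 0, 5))
  expect_equal(m$length_mm, 2)
  expect_equal(m$pennation_deg, 0)

  # square wave is longer than its chord
  sq <- rbind(c(0, 0, 0), c(0, 1, 1), c(0, 0, 2), c(0, 1, 3), c(0, 0, 4))
  msq <- digitised_polyline_metrics(sq, c(0, 0, 0), c(0, 0, 1))
  expect_gt(msq$length_mm, 4)

  # duplicate consecutive points are collapsed and counted
  dup <- rbind(c(0, 0, 0), c(0, 0, 1), c(0, 0, 1), c(0, 0, 2))
  mdup <- digitised_polyline_metrics(dup, c(0, 0, 0), c(0, 0, 1))
  expect_equal(mdup$length_mm, 2)
  expect_equal(mdup$n_duplicates_collapsed, 1L)

  # digitised arc at ~1 mm spacing: length within 1% of the true arc length
  R <- 20
  arc_len <- pi * R
  nseg <- ceiling(arc_len)
  phi <- seq(0, pi, length.out = nseg + 1)
  arc <- cbind(R * cos(phi), R * sin(phi), 0)
  ma <- digitised_polyline_metrics(arc, c(0, 0, 0), c(1, 0, 0))
  expect_equal(ma$length_mm, arc_len, tolerance = 0.01)

  expect_error(digitised_polyline_metrics(pts[1, , drop = FALSE],
                                          c(0, 0, 0), c(0, 0, 1)),
               "2 points")
})

test_that("extrapolation recovers truth and reduces length variability on phantom tracts", {
  ph <- small_slab_phantom()
  em <- small_slab_eigen()
  masks <- small_slab_masks()[["1"]]
  sl <- memo("small_slab_sl",
             track_compartment(em, masks,
                               tracking_params(n_target = 120, rng_seed = 9L)))
  fas <- memo("small_slab_fas",
              reconstruct_fascicles(sl, ph$meshes[["1"]], slab_axis(), "C1"))
  acc <- fas[fas$accepted, ]
  expect_gt(nrow(acc), 50)
  expect_equal(mean(acc$length_mm), ph$truth$fascicle_length_mm,
               tolerance = 0.03)
  expect_lt(abs(mean(acc$pennation_deg) - ph$truth$pennation_deg), 1)
  raw_len <- vapply(sl, `[[`, numeric(1), "length_mm")[fas$accepted]
  expect_lt(stats::var(acc$length_mm), stats::var(raw_len))
})

test_that("arc fascicles are longer than their chords", {
  R <- 58.8
  phi <- seq(-0.35, 0.35, length.out = 41)
  pts <- cbind(R * sin(phi), 0, R * (1 - cos(phi)))
  cv <- fit_polynomial(pts)
  chord <- sqrt(sum((pts[41, ] - pts[1, ])^2))
  expect_gt(cv$fitted_length_mm, chord)
})
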