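# surface models, volumes, long axis, seed/boundary masks, reliability

test_that("mesh volume matches closed forms on cube and icosphere", {
  mask <- array(TRUE, c(10, 10, 10))
  cube <- surface_from_mask(mask, affine_from_spacing(c(1, 1, 1)))
  expect_true(mesh_is_closed(cube))
  expect_equal(mesh_volume(cube), 1, tolerance = 1e-12)  # 1000 mm^3 = 1 cm^3

  unit_vox <- array(TRUE, c(1, 1, 1))
  unit_cube <- surface_from_mask(unit_vox, diag(4))
  expect_equal(mesh_volume(unit_cube), 0.001, tolerance = 1e-12)

  sph <- icosphere(radius = 10, subdivisions = 4)
  expect_true(mesh_is_closed(sph))
  expect_equal(mesh_volume(sph), 4 / 3 * pi * 1e3 / 1e3, tolerance = 0.005)

  flipped <- surface_mesh(sph$vertices, sph$faces[, c(1, 3, 2)])
  expect_equal(mesh_volume(flipped), mesh_volume(sph), tolerance = 1e-12)
})

test_that("open meshes raise an error listing boundary edges", {
  sph <- icosphere(1, 1)
  open_mesh <- surface_mesh(sph$vertices, sph$faces[-1, ])
  expect_error(mesh_volume(open_mesh), "not closed")
})

test_that("surface extraction volume equals the voxel-count volume exactly", {
  # anisotropic voxels, matching the DTI grid
  vox <- c(1.875, 1.875, 5)
  mask <- array(FALSE, c(12, 10, 8))
  mask[3:9, 2:8, 2:6] <- TRUE
  m <- surface_from_mask(mask, affine_from_spacing(vox))
  expect_true(mesh_is_closed(m))
  expect_equal(mesh_volume(m), sum(mask) * prod(vox) / 1000, tolerance = 1e-12)
  expect_gt(myotract:::mesh_signed_volume_mm3(m), 0)  # outward orientation

  # property: random blobby masks
  set.seed(99)
  for (rep in 1:3) {
    mk <- array(stats::runif(8 * 8 * 8) < 0.4, c(8, 8, 8))
    mk[4, 4, 4] <- TRUE
    m2 <- surface_from_mask(mk, affine_from_spacing(c(2, 1, 3)))
    expect_true(mesh_is_closed(m2))
    expect_equal(mesh_volume(m2), sum(mk) * 6 / 1000, tolerance = 1e-12)
  }
})

test_that("build_surface validates labels and warns on split components", {
  arr <- array(0L, c(6, 6, 6))
  arr[2:3, 2:3, 2:3] <- 1L
  labels <- label_volume(arr, diag(4))
  expect_error(build_surface(labels, 7), "empty")
  m <- build_surface(labels, 1)
  expect_equal(mesh_volume(m) * 1000, 8, tolerance = 1e-12)

  arr2 <- arr
  arr2[5, 5, 5] <- 1L
  expect_warning(build_surface(label_volume(arr2, diag(4)), 1),
                 "connected component")
})

test_that("slab phantom surface volume is within 2% of the analytic slab volume", {
  # isotropic voxels: discretisation error well below the 2% contract
  cs <- compartment_spec(1, pennation_deg = 30, thickness_mm = 20,
                         origin = c(4, 4, 10), extent_mm = c(30, 25))
  spec <- phantom_spec(c(30, 34, 110), voxel_size = c(1, 1, 1),
                       compartments = list(cs))
  ph <- generate_phantom(spec)
  expect_equal(mesh_volume(ph$meshes[["1"]]), ph$truth$volume_cm3,
               tolerance = 0.02)
  # anisotropic 1.875 x 1.875 x 5 mm grid: tilted end-caps beat against the
  # 5 mm slices, so the bound is looser (documented in the vignette); the
  # mesh still equals the voxel-count volume exactly
  ph2 <- small_slab_phantom()
  expect_equal(mesh_volume(ph2$meshes[["1"]]), ph2$truth$volume_cm3,
               tolerance = 0.05)
  expect_equal(mesh_volume(ph2$meshes[["1"]]),
               sum(ph2$labels$data == 1) * prod(ph2$spec$voxel_size) / 1000,
               tolerance = 1e-12)
})

test_that("muscle length projects combined vertices on the long axis", {
  cube1 <- surface_from_mask(array(TRUE, c(1, 1, 1)), diag(4))
  axis_z <- long_axis(c(0, 0, 10), c(0, 0, 0))
  expect_equal(muscle_length(list(cube1), axis_z), 1)

  shifted <- cube1
  shifted$vertices[, 3] <- shifted$vertices[, 3] + 50
  expect_equal(muscle_length(list(cube1, shifted), axis_z), 51)

  # axis orthogonal to the offset sees only the single-cube extent
  axis_x <- long_axis(c(10, 0, 0), c(0, 0, 0))
  expect_equal(muscle_length(list(cube1, shifted), axis_x), 1)

  # rigid translation invariance
  t1 <- cube1; t1$vertices <- t1$vertices + 7.3
  t2 <- shifted; t2$vertices <- t2$vertices + 7.3
  expect_equal(muscle_length(list(t1, t2), axis_z), 51, tolerance = 1e-12)

  expect_error(long_axis(c(1, 1, 1), c(1, 1, 1)), "distinct")
})

test_that("seed and boundary masks partition the compartment", {
  masks <- small_slab_masks()[["1"]]
  expect_identical(masks$seed | masks$boundary, masks$compartment)
  expect_false(any(masks$seed & masks$boundary))
  expect_true(all(which(masks$seed) %in% which(masks$compartment)))
})

test_that("boundary layer follows the 2-voxel Chebyshev rule on a slab", {
  # 5-voxel slab: erosion by 2 leaves a single-voxel seed sheet
  arr <- array(0L, c(12, 9, 9))
  arr[4:8, , ] <- 1L
  labels <- label_volume(arr, diag(4))
  masks <- make_seed_and_boundary_masks(labels, diag(4), c(12, 9, 9))
  seed <- masks[["1"]]$seed
  idx <- which(seed, arr.ind = TRUE)
  expect_true(all(idx[, 1] == 6))
  # interior cross-section (away from y/z faces, also eroded by 2)
  expect_equal(sum(seed[6, 3:7, 3:7]), 25)

  # 4-voxel slab: erosion swallows everything
  arr4 <- array(0L, c(12, 9, 9))
  arr4[4:7, , ] <- 1L
  expect_error(
    make_seed_and_boundary_masks(label_volume(arr4, diag(4)), diag(4),
                                 c(12, 9, 9)),
    "too thin"
  )
})

test_that("identity resampling preserves the label volume", {
  arr <- array(0L, c(6, 6, 6))
  arr[2:4, 2:4, 2:4] <- 3L
  labels <- label_volume(arr, affine_from_spacing(c(1.875, 1.875, 5)))
  res <- resample_labels(labels, labels$affine, dim(arr))
  expect_identical(res$data, arr)
})

test_that("nearest-neighbour resampling maps anatomical to DTI grids", {
  # anatomical grid at half the DTI spacing, same world frame
  ana_aff <- affine_from_spacing(c(1, 1, 1))
  dti_aff <- affine_from_spacing(c(2, 2, 2))
  arr <- array(0L, c(20, 20, 20))
  arr[5:16, 5:16, 5:16] <- 1L
  res <- resample_labels(label_volume(arr, ana_aff), dti_aff, c(10, 10, 10))
  # world box [4, 16]^3; DTI voxel centres at 1, 3, .., 19
  expect_equal(sum(res$data == 1), 6^3)
})

test_that("volume reliability matches hand-computed RMS values", {
  r0 <- volume_reliability(c(a = 5, b = 7), c(a = 5, b = 7))
  expect_equal(r0$rms_cm3, 0)
  expect_equal(r0$rms_pct, 0)

  r <- volume_reliability(c(a = 10, b = 10), c(a = 12, b = 8))
  expect_equal(r$rms_cm3, 2)
  expect_equal(r$rms_pct, 20)

  r1 <- volume_reliability(c(x = 100), c(x = 90))
  expect_equal(r1$rms_cm3, 10)

  expect_error(volume_reliability(c(a = 1, b = 2), c(a = 1, c = 2)),
               "unpaired")
})
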