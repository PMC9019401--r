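test_that("make_phantom realizes background, layers and inclusions in order", {
  # constant field
  vol <- make_phantom(phantom_spec(grid_shape = c(6, 6, 6),
                                   background_delta = 1,
                                   spacing = c(1, 1, 1)))
  expect_true(all(vol$values == 1))
  expect_identical(vol$max_delta, 1)

  # two-layer split at mid-depth: voxels partition exactly into the two values
  vol <- layered_volume(lo = 1, hi = 3, boundary = 8, dims = c(8, 8, 16))
  z <- (seq_len(16) - 1) * 1
  expect_true(all(vol$values[, , z < 8] == 1))
  expect_true(all(vol$values[, , z >= 8] == 3))
  expect_identical(vol$max_delta, 3)

  # a later layer overrides an earlier one where they overlap
  vol <- make_phantom(phantom_spec(
    grid_shape = c(4, 4, 12), background_delta = 1, spacing = c(1, 1, 1),
    layers = list(list(boundary = 4, delta = 2),
                  list(boundary = 8, delta = 5))))
  expect_equal(unique(as.vector(vol$values[1, 1, ])), c(1, 2, 5))

  # spherical inclusion overrides layers
  vol <- make_phantom(phantom_spec(
    grid_shape = c(11, 11, 11), background_delta = 1, spacing = c(1, 1, 1),
    inclusions = list(list(center = c(5, 5, 5), radii = 2, delta = 4,
                           shape = "sphere"))))
  expect_identical(vol$values[6, 6, 6], 4)   # centre voxel
  expect_identical(vol$values[1, 1, 1], 1)   # far corner untouched
  expect_identical(vol$values[6, 6, 9], 1)   # just outside radius 2
})

test_that("phantom noise is seeded, clipped at zero, and bitwise reproducible", {
  spec <- phantom_spec(grid_shape = c(10, 10, 10), background_delta = 0.5,
                       noise_sd = 1, seed = 42L, spacing = c(1, 1, 1))
  v1 <- make_phantom(spec)
  v2 <- make_phantom(spec)
  expect_identical(v1$values, v2$values)
  expect_true(all(v1$values >= 0))          # clipped after noise
  expect_true(any(v1$values == 0))          # sd 1 on background 0.5 must clip
  v3 <- make_phantom(phantom_spec(grid_shape = c(10, 10, 10),
                                  background_delta = 0.5, noise_sd = 1,
                                  seed = 43L, spacing = c(1, 1, 1)))
  expect_false(identical(v1$values, v3$values))
})

test_that("phantom generation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(make_phantom(phantom_spec(grid_shape = c(4, 4, 4), noise_sd = 1,
                                      seed = 7L, spacing = c(1, 1, 1))))
  expect_identical(runif(1), before)
})

test_that("phantom_spec rejects invalid configurations", {
  expect_error(phantom_spec(grid_shape = c(0, 4, 4)), "positive")
  expect_error(phantom_spec(noise_sd = -1), "noise_sd")
  expect_error(phantom_spec(layers = list(list(boundary = 5, delta = 1),
                                          list(boundary = 5, delta = 2))),
               "strictly increasing")
  expect_error(phantom_spec(inclusions = list(list(center = c(1, 1, 1),
                                                   radii = 0, delta = 1,
                                                   shape = "sphere"))),
               "radii")
  expect_error(attenuation_volume(array(-1, c(2, 2, 2))), ">= 0")
  expect_error(attenuation_volume(array(1, c(2, 2, 2)), spacing = c(1, 0, 1)),
               "positive")
})

test_that("estimate_gradient recovers analytic derivatives of linear fields", {
  # constant field: zero everywhere, including corners and faces
  vol <- uniform_volume(2, dims = c(4, 5, 6))
  for (idx in list(c(0, 0, 0), c(3, 4, 5), c(1, 2, 3), c(0, 2, 5)))
    expect_identical(estimate_gradient(vol, idx), c(0, 0, 0))

  # linear ramp along z with anisotropic spacing: central differences are
  # exact for linear fields, one-sided differences exact at the faces
  a <- 0.7
  vol <- ramp_volume(a = a, dims = c(5, 5, 12), spacing = c(0.59, 0.59, 0.6))
  expect_equal(estimate_gradient(vol, c(2, 2, 5)), c(0, 0, a))
  expect_equal(estimate_gradient(vol, c(2, 2, 0)), c(0, 0, a))   # low face
  expect_equal(estimate_gradient(vol, c(2, 2, 11)), c(0, 0, a))  # high face

  expect_error(estimate_gradient(vol, c(5, 0, 0)), "out of bounds")
  expect_error(estimate_gradient(vol, c(0, 0, -1)), "out of bounds")
})

test_that("estimate_gradient agrees with the vectorized gradient field", {
  vol <- make_phantom(phantom_spec(grid_shape = c(7, 6, 9),
                                   background_delta = 1, noise_sd = 0.5,
                                   seed = 3L, spacing = c(0.5, 1, 2)))
  gf <- sonosim:::gradient_field(vol)
  for (idx in list(c(0, 0, 0), c(6, 5, 8), c(3, 2, 4), c(0, 3, 8))) {
    g <- estimate_gradient(vol, idx)
    i <- idx + 1
    expect_equal(g, c(gf[[1]][i[1], i[2], i[3]], gf[[2]][i[1], i[2], i[3]],
                      gf[[3]][i[1], i[2], i[3]]))
  }
})

test_that("NIfTI round trip preserves values, spacing and origin", {
  vol <- make_phantom(phantom_spec(grid_shape = c(6, 7, 8),
                                   background_delta = 1, noise_sd = 0.3,
                                   seed = 11L, spacing = c(0.59, 0.59, 0.6),
                                   origin = c(1, -2, 3.5)))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(vol, f)
  back <- read_volume(f)
  expect_equal(back$values, vol$values)
  # header zooms/offsets are float32: compare at storage precision
  expect_equal(back$spacing, c(0.59, 0.59, 0.6), tolerance = 1e-6)
  expect_equal(back$origin, c(1, -2, 3.5), tolerance = 1e-6)
  expect_equal(back$max_delta, vol$max_delta)
})

test_that("read_volume rejects non-3D input with a format error", {
  f <- withr::local_tempfile(fileext = ".nii.gz")
  img <- RNifti::asNifti(matrix(1, 4, 4))  # 2D image
  RNifti::writeNifti(img, f)
  expect_error(read_volume(f), "format error.*3D")
  expect_error(read_volume("/nonexistent/vol.nii"), "not found")
})

test_that("phantom specs round-trip through JSON", {
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    grid_shape = c(8, 8, 16), background_delta = 1,
    layers = list(list(boundary = 8, delta = 3)),
    inclusions = list(list(center = c(4, 4, 4), radii = 1.5, delta = 2)),
    noise_sd = 0.1, seed = 5, spacing = c(1, 1, 1)), f, auto_unbox = TRUE)
  spec <- read_phantom_spec(f)
  expect_s3_class(spec, "phantom_spec")
  expect_identical(spec$grid_shape, c(8L, 8L, 16L))
  expect_identical(spec$layers[[1]]$delta, 3)
  expect_identical(spec$inclusions[[1]]$shape, "sphere")  # default shape
  vol <- make_phantom(spec)
  expect_identical(vol$values, make_phantom(spec)$values)
})
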