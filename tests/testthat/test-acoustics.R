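test_that("acoustic impedance is the density-speed product", {
  expect_identical(acoustic_impedance(0, 1540), 0)
  expect_identical(acoustic_impedance(1000, 1540), 1.54e6)
  # homogeneity
  expect_identical(acoustic_impedance(2000, 1540),
                   2 * acoustic_impedance(1000, 1540))
  expect_error(acoustic_impedance(-1, 10), ">= 0")
  expect_error(acoustic_impedance(10, -1), ">= 0")
})

test_that("specular reflection is the squared mismatch ratio, symmetric", {
  expect_identical(specular_reflection(2, 2), 0)
  expect_equal(specular_reflection(1, 3), 0.25)  # ((3-1)/(3+1))^2
  set.seed(1)
  for (i in 1:20) {
    q <- runif(2, 0, 1e7)
    expect_identical(specular_reflection(q[1], q[2]),
                     specular_reflection(q[2], q[1]))
    expect_all_in(specular_reflection(q[1], q[2]), 0, 1)
  }
  expect_error(specular_reflection(0, 0), "> 0")
  expect_error(specular_reflection(-1, 2), ">= 0")
})

test_that("diffuse reflection applies the cosine falloff", {
  # theta = 0: reduces to the specular coefficient for any exponent
  for (n in c(0, 1, 2, 5))
    expect_equal(diffuse_reflection(1, 3, 0, n), specular_reflection(1, 3))
  # grazing incidence kills the echo for n >= 1
  expect_identical(diffuse_reflection(1, 3, pi / 2, 1), 0)
  expect_identical(diffuse_reflection(1, 3, pi / 2, 4), 0)
  # direct evaluation: cos(pi/3)^2 * 0.25 = 0.0625
  expect_equal(diffuse_reflection(1, 3, pi / 3, 2), 0.0625)
  # nonincreasing in theta
  thetas <- seq(0, pi / 2, length.out = 30)
  r <- diffuse_reflection(1, 4, thetas, 2)
  expect_true(all(diff(r) <= 1e-12))
  expect_error(diffuse_reflection(1, 3, -0.1, 1), "theta")
  expect_error(diffuse_reflection(1, 3, 2, 1), "theta")
  expect_error(diffuse_reflection(1, 3, 0.5, -1), "n")
})

test_that("gradient reflection vanishes without a forward-facing gradient", {
  vol <- uniform_volume(2)
  expect_identical(gradient_reflection(vol, c(3, 3, 3), c(0, 0, 1)), 0)

  # planar interface along z: beam orthogonal to the interface normal
  vol <- layered_volume()
  expect_identical(gradient_reflection(vol, c(3, 3, 8), c(1, 0, 0)), 0)
  # back-facing: beam pointing away from increasing delta
  expect_identical(gradient_reflection(vol, c(3, 3, 8), c(0, 0, -1)), 0)
  expect_error(gradient_reflection(vol, c(100, 3, 3), c(0, 0, 1)), "outside")
})

test_that("gradient reflection and transmittance share the normalizer", {
  # ramp with gradient a = max_delta: R(n=1) = 0.5, t = 0.75
  vol <- ramp_volume(a = 1, dims = c(5, 5, 11), spacing = c(1, 1, 0.1))
  # values run 0..1 mm-scaled: delta = z, max at z = 1, |grad| = 1 = max_delta
  expect_equal(vol$max_delta, 1)
  p <- c(2, 2, 0.5)
  expect_equal(gradient_reflection(vol, p, c(0, 0, 1), n = 1), 0.5)
  expect_equal(transmittance(vol, p), 0.75)

  # shared-normalizer identity on a rough random phantom:
  # (|grad| / (2 max_delta))^2 == 1 - t at matching points
  vol <- make_phantom(phantom_spec(grid_shape = c(9, 9, 9),
                                   background_delta = 2, noise_sd = 0.4,
                                   seed = 8L, spacing = c(1, 1, 1)))
  set.seed(2)
  for (i in 1:25) {
    p <- runif(3, 0.5, 7.5)
    g <- sonosim:::.gradient_at(vol, matrix(p, 1, 3))
    lhs <- (sqrt(sum(g^2)) / (2 * vol$max_delta))^2
    expect_equal(lhs, 1 - transmittance(vol, p), tolerance = 1e-12)
    # R with a forward unit direction stays in range
    d <- g / max(sqrt(sum(g^2)), 1e-12)
    expect_all_in(gradient_reflection(vol, p, as.numeric(d), n = 1), 0, 1)
  }
})

test_that("transmittance hits its extreme values", {
  expect_identical(transmittance(uniform_volume(3), c(3, 3, 3)), 1)
  # |grad| = 2 max_delta -> t = 0: steep sawtooth exceeding the bound is
  # clamped; construct |grad| exactly 2*max via a ramp with small extent
  vol <- ramp_volume(a = 2, dims = c(4, 4, 11), spacing = c(1, 1, 0.1))
  # delta = 2z, z in [0,1]; max_delta = 2; |grad|/(2 max) = 2/4 -> t = 0.75
  expect_equal(transmittance(vol, c(1, 1, 0.5)), 0.75)
})

test_that("attenuation ratio matches the closed form on constant-gradient fields", {
  # ramp: |grad| = a everywhere inside, so over a segment of length L the
  # integral is (a / (2 max))^2 * L exactly
  a <- 0.8
  vol <- ramp_volume(a = a, dims = c(6, 6, 40), spacing = c(1, 1, 1))
  maxd <- vol$max_delta
  r <- ray(c(2, 2, 2), c(0, 0, 1), step = 0.5)
  for (L in c(1, 5, 17.3)) {
    expect_equal(attenuation_ratio(vol, r, L),
                 exp(-(a / (2 * maxd))^2 * L), tolerance = 1e-6)
  }
  # against a 100x finer-step numerical integration
  fine <- ray(c(2, 2, 2), c(0, 0, 1), step = 0.005)
  expect_equal(attenuation_ratio(vol, r, 20),
               attenuation_ratio(vol, fine, 20), tolerance = 1e-9)
})

test_that("attenuation ratio is 1 at depth 0 and in homogeneous media", {
  vol <- uniform_volume(5, dims = c(8, 8, 20))
  r <- ray(c(3, 3, 1), c(0, 0, 1), step = 0.25)
  expect_identical(attenuation_ratio(vol, r, 0), 1)
  expect_identical(attenuation_ratio(vol, r, 15), 1)
})

test_that("attenuation ratio composes multiplicatively along the ray", {
  vol <- make_phantom(phantom_spec(grid_shape = c(8, 8, 30),
                                   background_delta = 2, noise_sd = 0.5,
                                   seed = 21L, spacing = c(1, 1, 1)))
  d <- c(0, 0, 1)
  r1 <- ray(c(3, 3, 1), d, step = 0.5)
  L1 <- 10; L2 <- 8
  whole <- attenuation_ratio(vol, r1, L1 + L2)
  first <- attenuation_ratio(vol, r1, L1)
  cont <- attenuation_ratio(vol, ray(c(3, 3, 1) + L1 * d, d, step = 0.5), L2)
  expect_equal(whole, first * cont, tolerance = 1e-12)
})

test_that("attenuation ratio is monotone nonincreasing in depth", {
  vol <- make_phantom(phantom_spec(grid_shape = c(8, 8, 30),
                                   background_delta = 1, noise_sd = 0.6,
                                   seed = 31L, spacing = c(1, 1, 1)))
  r <- ray(c(3.5, 3.5, 0.5), c(0, 0, 1), step = 0.3)
  depths <- seq(0, 25, by = 0.7)
  vals <- vapply(depths, function(L) attenuation_ratio(vol, r, L), numeric(1))
  expect_true(all(diff(vals) <= 1e-12))
  expect_all_in(vals, 0, 1)
})

test_that("attenuation ratio converges under step refinement on smooth phantoms", {
  vol <- make_phantom(phantom_spec(
    grid_shape = c(10, 10, 30), background_delta = 1, spacing = c(1, 1, 1),
    inclusions = list(list(center = c(5, 5, 15), radii = c(4, 4, 8),
                           delta = 3, shape = "ellipsoid"))))
  o <- c(4.5, 4.5, 1)
  coarse <- attenuation_ratio(vol, ray(o, c(0, 0, 1), step = 0.5), 25)
  fine <- attenuation_ratio(vol, ray(o, c(0, 0, 1), step = 0.05), 25)
  expect_equal(coarse, fine, tolerance = 0.01)
})

test_that("rays leaving the volume raise an error naming the exit depth", {
  vol <- uniform_volume(1, dims = c(8, 8, 8))
  r <- ray(c(3, 3, 5), c(0, 0, 1), step = 0.5)
  expect_error(attenuation_ratio(vol, r, 10), "exits the volume at depth 10")
  expect_error(attenuation_ratio(vol, r, -1), ">= 0")
})

test_that("ray constructor enforces the unit-direction invariant", {
  expect_error(ray(c(0, 0, 0), c(0, 0, 2)), "unit vector")
  expect_error(ray(c(0, 0, 0), c(0, 0, 1), step = 0), "positive")
  d <- c(1, 1, 1) / sqrt(3)
  expect_s3_class(ray(c(0, 0, 0), d), "ray")
})
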