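# Shared fixture builders: every volume is generated in code at test time.

# Uniform field of value `v`
uniform_volume <- function(v = 1, dims = c(8, 8, 8), spacing = c(1, 1, 1)) {
  attenuation_volume(array(v, dims), spacing = spacing)
}

# Linear ramp along axis 3: delta = a * z (mm), offset to keep delta >= 0
ramp_volume <- function(a = 0.5, dims = c(6, 6, 20), spacing = c(1, 1, 1),
                        offset = 0) {
  z <- (seq_len(dims[3]) - 1) * spacing[3]
  vals <- array(rep(offset + a * z, each = dims[1] * dims[2]), dims)
  attenuation_volume(vals, spacing = spacing)
}

# Two-layer phantom: delta = lo above `boundary` (mm along axis 3), hi below
layered_volume <- function(lo = 1, hi = 3, boundary = 8,
                           dims = c(8, 8, 16), spacing = c(1, 1, 1)) {
  make_phantom(phantom_spec(grid_shape = dims, background_delta = lo,
                            layers = list(list(boundary = boundary,
                                               delta = hi)),
                            spacing = spacing))
}

# Phantom with a high-gradient absorber band: thin alternating layers of
# low/high attenuation spanning [band_start, band_start + n_pairs * 2 * th]
# along the beam axis. Drives the accumulated intensity ratio down sharply.
absorber_band_phantom <- function(dims = c(64, 64, 64),
                                  spacing = c(0.59, 0.59, 0.6),
                                  band_start = 15, thickness = 1.2,
                                  n_pairs = 3, lo = 1, hi = 5) {
  layers <- list()
  z <- band_start
  for (i in seq_len(n_pairs)) {
    layers <- c(layers, list(list(boundary = z, delta = hi),
                             list(boundary = z + thickness, delta = lo)))
    z <- z + 2 * thickness
  }
  make_phantom(phantom_spec(grid_shape = dims, background_delta = lo,
                            layers = layers, spacing = spacing))
}

expect_all_in <- function(x, lo, hi) {
  expect_true(all(x >= lo & x <= hi))
}
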