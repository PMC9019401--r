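#' Attenuation volume
#'
#' The medium every acoustic operation reads: a 3D non-negative scalar field
#' of per-voxel attenuation values \eqn{\delta(\vec{x})} on a regular grid
#' with physical voxel spacing. The global maximum of \eqn{\delta} is cached
#' at construction because it normalizes every reflection, transmittance and
#' attenuation computation.
#'
#' Voxel indexing is 0-based in physical terms: the centre of voxel
#' `values[i, j, k]` (1-based R subscript) sits at
#' `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @param values numeric 3D array of attenuation values, all `>= 0`.
#' @param spacing numeric length-3, physical voxel step per axis in mm,
#'   all `> 0`. Default `c(0.59, 0.59, 0.6)` mm: a 0.6 mm slice spacing
#'   with a 0.59 mm in-plane pixel pitch, matching the clinical
#'   acquisitions this simulator emulates (the in-plane pitch is
#'   conventionally quoted unitless; mm is assumed to match the slice
#'   spacing).
#' @param origin numeric length-3, physical coordinate (mm) of voxel
#'   `[1, 1, 1]`'s centre.
#' @return An object of class `attenuation_volume` with fields `values`,
#'   `spacing`, `origin` and `max_delta`.
#' @examples
#' vol <- attenuation_volume(array(1, c(4, 4, 4)))
#' vol$max_delta
#' @export
attenuation_volume <- function(values, spacing = c(0.59, 0.59, 0.6),
                               origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  storage.mode(values) <- "double"
  if (anyNA(values) || any(values < 0))
    stop("attenuation values must be finite and >= 0", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive numbers (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers (mm)", call. = FALSE)
  structure(
    list(values = values, spacing = spacing, origin = origin,
         max_delta = max(values), .cache = new.env(parent = emptyenv())),
    class = "attenuation_volume"
  )
}

#' @export
print.attenuation_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<attenuation_volume> %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  delta range [%g, %g], origin (%g, %g, %g) mm\n",
              min(x$values), x$max_delta,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Phantom specification
#'
#' Declarative description of a synthetic tissue phantom: a constant
#' background attenuation, overwritten in order by axis-aligned layers
#' (stacked along the third axis), then by ellipsoidal or spherical
#' inclusions, then optional additive Gaussian texture noise clipped at
#' zero.
#'
#' @param grid_shape integer length-3, voxel counts per axis. The default,
#'   `c(521, 512, 344)`, mirrors the clinical volumes the simulator stands
#'   in for; the 521 is plausibly a transcription artifact of 512 but is
#'   kept rather than silently corrected. Tests and examples use much
#'   smaller grids.
#' @param background_delta scalar background attenuation, `>= 0`.
#' @param layers list of `list(boundary = <mm>, delta = <value>)`: each
#'   layer sets `delta` for all voxels whose third-axis physical coordinate
#'   is `>= boundary`. Boundaries must be strictly increasing.
#' @param inclusions list of `list(center = <mm xyz>, radii = <mm, length
#'   1 or 3>, delta = <value>, shape = "sphere"|"ellipsoid")`.
#' @param noise_sd standard deviation of additive Gaussian texture noise
#'   (attenuation units); `0` disables it.
#' @param seed integer seed making the noise reproducible.
#' @param spacing,origin passed through to [attenuation_volume()].
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(521, 512, 344),
                         background_delta = 1,
                         layers = list(),
                         inclusions = list(),
                         noise_sd = 0,
                         seed = 1L,
                         spacing = c(0.59, 0.59, 0.6),
                         origin = c(0, 0, 0)) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || anyNA(grid_shape) || any(grid_shape <= 0L))
    stop("`grid_shape` must be 3 positive integers", call. = FALSE)
  if (!is.numeric(background_delta) || background_delta < 0)
    stop("`background_delta` must be >= 0", call. = FALSE)
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0)
    stop("`noise_sd` must be a single value >= 0", call. = FALSE)
  bounds <- vapply(layers, function(l) as.numeric(l$boundary), numeric(1))
  if (length(bounds) > 1L && any(diff(bounds) <= 0))
    stop("layer boundaries must be strictly increasing", call. = FALSE)
  for (l in layers)
    if (l$delta < 0) stop("layer delta must be >= 0", call. = FALSE)
  for (inc in inclusions) {
    if (inc$delta < 0) stop("inclusion delta must be >= 0", call. = FALSE)
    if (any(inc$radii <= 0)) stop("inclusion radii must be > 0", call. = FALSE)
  }
  structure(
    list(grid_shape = grid_shape, background_delta = background_delta,
         layers = layers, inclusions = inclusions, noise_sd = noise_sd,
         seed = as.integer(seed), spacing = as.numeric(spacing),
         origin = as.numeric(origin)),
    class = "phantom_spec"
  )
}

#' Generate a synthetic attenuation phantom
#'
#' Realizes a [phantom_spec()]: background, then layers in order, then
#' inclusions, then optional seeded Gaussian noise clipped at zero so the
#' attenuation field stays non-negative. Deterministic for a given spec
#' (the seed is part of the spec).
#'
#' @param spec a [phantom_spec()].
#' @return An [attenuation_volume()].
#' @examples
#' spec <- phantom_spec(grid_shape = c(8, 8, 16), background_delta = 1,
#'                      layers = list(list(boundary = 5, delta = 3)),
#'                      spacing = c(1, 1, 1))
#' vol <- make_phantom(spec)
#' range(vol$values)
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  vals <- array(spec$background_delta, dim = d)

  # physical coordinate of each voxel centre along axis 3
  z <- spec$origin[3] + (seq_len(d[3]) - 1) * spec$spacing[3]
  for (l in spec$layers) {
    sel <- z >= l$boundary
    if (any(sel)) vals[, , sel] <- l$delta
  }

  if (length(spec$inclusions) > 0) {
    x <- spec$origin[1] + (seq_len(d[1]) - 1) * spec$spacing[1]
    y <- spec$origin[2] + (seq_len(d[2]) - 1) * spec$spacing[2]
    for (inc in spec$inclusions) {
      r <- rep_len(as.numeric(inc$radii), 3L)
      if (identical(inc$shape, "sphere")) r <- rep(r[1], 3L)
      u2 <- ((x - inc$center[1]) / r[1])^2
      v2 <- ((y - inc$center[2]) / r[2])^2
      w2 <- ((z - inc$center[3]) / r[3])^2
      inside <- outer(outer(u2, v2, `+`), w2, `+`) <= 1
      vals[inside] <- inc$delta
    }
  }

  if (spec$noise_sd > 0) {
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(spec$seed)
    vals <- vals + array(stats::rnorm(prod(d), sd = spec$noise_sd), dim = d)
    vals[vals < 0] <- 0
  }

  attenuation_volume(vals, spacing = spec$spacing, origin = spec$origin)
}

# save/restore the global RNG state so phantom generation is reproducible
# without clobbering the caller's random stream
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_set <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", seed, envir = globalenv())
}

#' Finite-difference gradient at a voxel
#'
#' Estimates the spatial gradient of the attenuation field at one voxel in
#' attenuation units per mm: central differences in the grid interior,
#' one-sided differences on boundary faces (one-sided rather than
#' zero-padded, so the volume edge does not masquerade as a tissue
#' interface).
#'
#' @param volume an [attenuation_volume()].
#' @param voxel_index integer length-3, 0-based voxel index.
#' @return numeric length-3 gradient vector (attenuation units / mm).
#' @examples
#' vol <- attenuation_volume(array(rep(1:6, each = 16), c(4, 4, 6)),
#'                           spacing = c(1, 1, 1))
#' estimate_gradient(vol, c(2, 2, 3))  # ramp of 1 per mm along axis 3
#' @export
estimate_gradient <- function(volume, voxel_index) {
  stopifnot(inherits(volume, "attenuation_volume"))
  idx <- as.integer(voxel_index)
  d <- dim(volume$values)
  if (length(idx) != 3L || anyNA(idx) || any(idx < 0L) || any(idx >= d))
    stop("voxel index out of bounds", call. = FALSE)
  i <- idx + 1L  # to 1-based
  g <- numeric(3)
  for (ax in 1:3) {
    lo <- i; hi <- i
    if (i[ax] == 1L) {            # low face: forward difference
      hi[ax] <- i[ax] + 1L
    } else if (i[ax] == d[ax]) {  # high face: backward difference
      lo[ax] <- i[ax] - 1L
    } else {                      # interior: central difference
      lo[ax] <- i[ax] - 1L; hi[ax] <- i[ax] + 1L
    }
    h <- (hi[ax] - lo[ax]) * volume$spacing[ax]
    g[ax] <- (volume$values[hi[1], hi[2], hi[3]] -
              volume$values[lo[1], lo[2], lo[3]]) / h
  }
  g
}

# Finite differences along one axis: central in the interior, one-sided
# on the two faces. Permutes the target axis to the front so the slicing
# is uniform.
.diff_axis <- function(v, ax, h) {
  perm <- c(ax, setdiff(1:3, ax))
  vp <- aperm(v, perm)
  n <- dim(vp)[1]
  gp <- array(0, dim = dim(vp))
  if (n > 1L) {
    if (n > 2L)
      gp[2:(n - 1L), , ] <- (vp[3:n, , ] - vp[1:(n - 2L), , ]) / (2 * h)
    gp[1L, , ] <- (vp[2L, , ] - vp[1L, , ]) / h
    gp[n, , ] <- (vp[n, , ] - vp[n - 1L, , ]) / h
  }
  aperm(gp, order(perm))
}

# Full gradient field, computed once per volume and memoized in the
# volume's cache environment. Returns a list of three arrays (d/dx, d/dy,
# d/dz), same dims as the volume, in attenuation units per mm.
gradient_field <- function(volume) {
  cache <- volume$.cache
  if (!is.null(cache$grad)) return(cache$grad)
  grad <- lapply(1:3, function(ax)
    .diff_axis(volume$values, ax, volume$spacing[ax]))
  cache$grad <- grad
  grad
}

#' Read an attenuation volume from NIfTI
#'
#' Reads a scalar 3D NIfTI volume; voxel spacing is taken from the header
#' zooms (mm) and the origin from the q-form offsets.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return An [attenuation_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("format error: expected a 3D scalar volume, got ",
         length(dim(img)), "D data", call. = FALSE)
  sp <- RNifti::pixdim(img)
  if (length(sp) < 3L || any(!is.finite(sp[1:3])) || any(sp[1:3] <= 0))
    stop("format error: header field `pixdim` does not give 3 positive ",
         "voxel spacings", call. = FALSE)
  hdr <- RNifti::niftiHeader(img)
  org <- c(hdr$qoffset_x, hdr$qoffset_y, hdr$qoffset_z)
  attenuation_volume(array(as.numeric(img), dim = dim(img)),
                     spacing = sp[1:3], origin = org)
}

#' Write an attenuation volume to NIfTI
#'
#' @param volume an [attenuation_volume()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "attenuation_volume"))
  img <- RNifti::asNifti(volume$values)
  RNifti::pixdim(img) <- volume$spacing
  aff <- diag(4)
  diag(aff)[1:3] <- volume$spacing
  aff[1:3, 4] <- volume$origin
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a phantom specification from JSON
#'
#' The JSON document mirrors the fields of [phantom_spec()]; absent fields
#' take the constructor defaults.
#'
#' @param path path to a JSON file.
#' @return A [phantom_spec()].
#' @export
read_phantom_spec <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  args <- list()
  for (f in c("grid_shape", "background_delta", "noise_sd", "seed",
              "spacing", "origin"))
    if (!is.null(doc[[f]])) args[[f]] <- unlist(doc[[f]])
  if (!is.null(doc$layers))
    args$layers <- lapply(doc$layers, function(l)
      list(boundary = as.numeric(l$boundary), delta = as.numeric(l$delta)))
  if (!is.null(doc$inclusions))
    args$inclusions <- lapply(doc$inclusions, function(i)
      list(center = as.numeric(unlist(i$center)),
           radii = as.numeric(unlist(i$radii)), delta = as.numeric(i$delta),
           shape = if (is.null(i$shape)) "sphere" else i$shape))
  do.call(phantom_spec, args)
}
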