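#' Acoustic ray
#'
#' A straight beam through the medium: physical origin, unit direction and
#' the marching step used to discretize the attenuation integral.
#'
#' @param origin numeric length-3 physical start point (mm).
#' @param direction numeric length-3 unit vector; its norm must be 1 within
#'   `1e-9`.
#' @param step marching increment \eqn{\lambda} in mm, `> 0`. Default 0.3 mm
#'   (half the finest default voxel pitch, so the integral sees every
#'   voxel).
#' @return An object of class `ray`.
#' @examples
#' ray(c(0, 0, 0), c(0, 0, 1))
#' @export
ray <- function(origin, direction, step = 0.3) {
  origin <- as.numeric(origin); direction <- as.numeric(direction)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers (mm)", call. = FALSE)
  if (length(direction) != 3L || any(!is.finite(direction)))
    stop("`direction` must be 3 finite numbers", call. = FALSE)
  if (abs(sqrt(sum(direction^2)) - 1) > 1e-9)
    stop("`direction` must be a unit vector (tolerance 1e-9)", call. = FALSE)
  if (!is.numeric(step) || length(step) != 1L || !is.finite(step) || step <= 0)
    stop("`step` must be a single positive number (mm)", call. = FALSE)
  structure(list(origin = origin, direction = direction, step = step),
            class = "ray")
}

#' Acoustic impedance
#'
#' Impedance of a medium point as the product of tissue density and sound
#' speed, \eqn{Q = \rho V}.
#'
#' @param rho tissue density (kg/m^3), `>= 0`.
#' @param v speed of sound (m/s), `>= 0`.
#' @return Impedance in kg m^-2 s^-1. Vectorized.
#' @examples
#' acoustic_impedance(1000, 1540)  # soft tissue, 1.54e6 rayl
#' @export
acoustic_impedance <- function(rho, v) {
  if (any(!is.finite(rho)) || any(rho < 0))
    stop("`rho` must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(v)) || any(v < 0))
    stop("`v` must be finite and >= 0", call. = FALSE)
  rho * v
}

#' Specular reflection coefficient
#'
#' Intensity reflection coefficient at the interface between two media of
#' impedances `q1` and `q2`: the squared impedance-mismatch ratio
#' \eqn{K = ((Q_2 - Q_1) / (Q_2 + Q_1))^2}. Symmetric in its arguments and
#' zero for matched impedances.
#'
#' @param q1,q2 acoustic impedances, `>= 0` with `q1 + q2 > 0`. Vectorized.
#' @return Reflection coefficient in `[0, 1)`.
#' @examples
#' specular_reflection(1, 3)  # 0.25
#' @export
specular_reflection <- function(q1, q2) {
  if (any(!is.finite(q1)) || any(!is.finite(q2)) || any(q1 < 0) || any(q2 < 0))
    stop("impedances must be finite and >= 0", call. = FALSE)
  if (any(q1 + q2 == 0))
    stop("q1 + q2 must be > 0", call. = FALSE)
  ((q2 - q1) / (q2 + q1))^2
}

#' Diffuse reflection coefficient
#'
#' Angle-dependent reflection at a rough interface:
#' \eqn{R = \cos^n\theta \cdot ((Q_2 - Q_1)/(Q_2 + Q_1))^2}. The exponent
#' `n` controls how sharply the returned echo falls off away from normal
#' incidence; different tissue interfaces scatter with different `n`.
#'
#' @param q1,q2 acoustic impedances as in [specular_reflection()].
#' @param theta incidence angle in radians, in `[0, pi/2]`.
#' @param n diffuse exponent, `>= 0`.
#' @return Reflection coefficient in `[0, 1)`; equals
#'   [specular_reflection()] at `theta = 0` and is nonincreasing in
#'   `theta`.
#' @examples
#' diffuse_reflection(1, 3, pi / 3, n = 2)  # 0.0625
#' @export
diffuse_reflection <- function(q1, q2, theta, n = 1) {
  if (any(!is.finite(theta)) || any(theta < 0) || any(theta > pi / 2))
    stop("`theta` must lie in [0, pi/2]", call. = FALSE)
  if (any(!is.finite(n)) || any(n < 0))
    stop("`n` must be >= 0", call. = FALSE)
  cosv <- cos(theta)
  cosv[abs(cosv) < 1e-15] <- 0  # cos(pi/2) is not exactly 0 in floating point
  cosv^n * specular_reflection(q1, q2)
}

# ---- field sampling ---------------------------------------------------

# Continuous (0-based) grid index of physical points; points is an n x 3
# matrix in mm.
.continuous_index <- function(volume, points) {
  ci <- sweep(points, 2, volume$origin, `-`)
  sweep(ci, 2, volume$spacing, `/`)
}

# Error if any continuous index falls outside the grid; `depths` (if
# given) lets the message name the offending ray depth.
.check_inside <- function(volume, ci, depths = NULL, tol = 1e-9) {
  d <- dim(volume$values)
  bad <- rep(FALSE, nrow(ci))
  for (ax in 1:3)
    bad <- bad | ci[, ax] < -tol | ci[, ax] > d[ax] - 1 + tol
  if (any(bad)) {
    k <- which(bad)[1]
    if (!is.null(depths))
      stop(sprintf("ray exits the volume at depth %.4g mm", depths[k]),
           call. = FALSE)
    stop("position outside the volume", call. = FALSE)
  }
  invisible(TRUE)
}

# Trilinear interpolation of one scalar array at continuous indices ci
# (n x 3, 0-based, assumed inside the grid).
.trilinear <- function(arr, ci) {
  d <- dim(arr)
  n <- nrow(ci)
  i0 <- matrix(0L, n, 3)
  f <- matrix(0, n, 3)
  for (ax in 1:3) {
    if (d[ax] > 1L) {
      i0[, ax] <- pmin(pmax(floor(ci[, ax]), 0), d[ax] - 2L)
      f[, ax] <- pmin(pmax(ci[, ax] - i0[, ax], 0), 1)
    }
  }
  out <- numeric(n)
  for (corner in 0:7) {
    dx <- bitwAnd(corner, 1L)
    dy <- bitwAnd(bitwShiftR(corner, 1L), 1L)
    dz <- bitwAnd(bitwShiftR(corner, 2L), 1L)
    w <- (if (dx) f[, 1] else 1 - f[, 1]) *
         (if (dy) f[, 2] else 1 - f[, 2]) *
         (if (dz) f[, 3] else 1 - f[, 3])
    idx <- (i0[, 1] + dx) + d[1] * ((i0[, 2] + dy) + d[2] * (i0[, 3] + dz)) + 1
    out <- out + w * arr[idx]
  }
  out
}

# Interpolated gradient vectors at physical points (n x 3 matrix, mm).
# Returns an n x 3 matrix in attenuation units per mm.
.gradient_at <- function(volume, points, depths = NULL) {
  ci <- .continuous_index(volume, points)
  .check_inside(volume, ci, depths)
  grad <- gradient_field(volume)
  cbind(.trilinear(grad[[1]], ci),
        .trilinear(grad[[2]], ci),
        .trilinear(grad[[3]], ci))
}

# Vectorized reflection and transmittance kernels used by the scanner.
.reflection_at <- function(volume, points, direction, n = 1, depths = NULL) {
  g <- .gradient_at(volume, points, depths)
  gnorm <- sqrt(rowSums(g^2))
  r <- numeric(nrow(points))
  live <- gnorm > 1e-12
  if (any(live)) {
    cosf <- as.numeric(g[live, , drop = FALSE] %*% direction) / gnorm[live]
    cosf[cosf < 0] <- 0  # back-facing interfaces reflect away from the probe
    r[live] <- cosf * (gnorm[live] / (2 * volume$max_delta))^n
  }
  pmin(r, 1)
}

.transmittance_at <- function(volume, points, depths = NULL) {
  g <- .gradient_at(volume, points, depths)
  gnorm <- sqrt(rowSums(g^2))
  pmax(1 - (gnorm / (2 * volume$max_delta))^2, 0)
}

# ---- public point kernels ---------------------------------------------

#' Gradient-based reflection coefficient
#'
#' Reflection at a point of an attenuation volume, driven by the local
#' attenuation gradient standing in for an impedance jump:
#' \deqn{R = \max(0, \hat{d} \cdot \nabla\delta / \|\nabla\delta\|) \cdot
#'       (\|\nabla\delta\| / (2 \max\delta))^n}
#' The cosine factor is clamped at zero (back-facing interfaces do not
#' reflect toward the probe) and the whole coefficient at one. Points where
#' \eqn{\|\nabla\delta\| < 10^{-12}} return exactly 0. \eqn{\max\delta} is
#' the cached global maximum of the volume.
#'
#' @param volume an [attenuation_volume()].
#' @param position numeric length-3 physical point (mm) inside the volume.
#' @param direction numeric length-3 unit beam direction.
#' @param n diffuse exponent, `>= 0`; default 1.
#' @return Reflection coefficient in `[0, 1]`.
#' @export
gradient_reflection <- function(volume, position, direction, n = 1) {
  stopifnot(inherits(volume, "attenuation_volume"))
  if (volume$max_delta <= 0)
    stop("volume has max_delta = 0; cannot normalize", call. = FALSE)
  if (abs(sqrt(sum(direction^2)) - 1) > 1e-9)
    stop("`direction` must be a unit vector", call. = FALSE)
  if (!is.finite(n) || n < 0) stop("`n` must be >= 0", call. = FALSE)
  .reflection_at(volume, matrix(as.numeric(position), 1, 3), direction, n)
}

#' Interface transmittance
#'
#' Fraction of beam intensity passing a point rather than being reflected:
#' \eqn{t = 1 - (\|\nabla\delta\| / (2 \max\delta))^2}, clamped to
#' `[0, 1]`. Equals 1 in homogeneous regions.
#'
#' @inheritParams gradient_reflection
#' @return Transmittance in `[0, 1]`.
#' @export
transmittance <- function(volume, position) {
  stopifnot(inherits(volume, "attenuation_volume"))
  if (volume$max_delta <= 0)
    stop("volume has max_delta = 0; cannot normalize", call. = FALSE)
  .transmittance_at(volume, matrix(as.numeric(position), 1, 3))
}

# Midpoint-rule discretization of the attenuation integral along a ray:
# returns sub-interval lengths and midpoint depths covering [0, depth].
.integral_steps <- function(step, depth) {
  m <- floor(depth / step + 1e-12)
  lens <- rep(step, m)
  rem <- depth - m * step
  if (rem > 1e-12) lens <- c(lens, rem)
  mids <- cumsum(lens) - lens / 2
  list(lens = lens, mids = mids)
}

#' Depth-accumulated attenuation ratio
#'
#' Remaining intensity fraction \eqn{I(X)/I_0} after the beam has travelled
#' `depth` mm along the ray:
#' \deqn{I/I_0 = \exp\left(-\int_0^{depth}
#'   \left(\frac{\|\nabla\delta(\vec{x} + \lambda\hat{d})\|}
#'              {2\max\delta}\right)^2 d\lambda\right)}
#' discretized by the midpoint rule at the ray's marching step, with the
#' gradient sampled by trilinear interpolation. The ratio is 1 at depth 0
#' and nonincreasing in depth.
#'
#' @param volume an [attenuation_volume()].
#' @param ray a [ray()]; its `step` sets the discretization.
#' @param depth distance along the ray in mm, `>= 0`. The whole segment
#'   must lie inside the volume.
#' @return Intensity ratio in `(0, 1]`.
#' @examples
#' vol <- attenuation_volume(array(1, c(8, 8, 8)), spacing = c(1, 1, 1))
#' attenuation_ratio(vol, ray(c(3, 3, 0), c(0, 0, 1), step = 0.5), 5)
#' @export
attenuation_ratio <- function(volume, ray, depth) {
  stopifnot(inherits(volume, "attenuation_volume"), inherits(ray, "ray"))
  if (!is.finite(depth) || depth < 0)
    stop("`depth` must be >= 0", call. = FALSE)
  if (depth == 0) return(1)
  # validate the segment endpoints, then integrate over midpoints
  ends <- rbind(ray$origin, ray$origin + depth * ray$direction)
  .check_inside(volume, .continuous_index(volume, ends), depths = c(0, depth))
  st <- .integral_steps(ray$step, depth)
  pts <- matrix(ray$origin, length(st$mids), 3, byrow = TRUE) +
    st$mids %o% ray$direction
  g <- .gradient_at(volume, pts, depths = st$mids)
  integrand <- (sqrt(rowSums(g^2)) / (2 * volume$max_delta))^2
  exp(-sum(integrand * st$lens))
}
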