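#' Linear-array scan geometry
#'
#' A set of parallel beams on a regular lateral grid, as emitted by a
#' linear-array probe: one shared beam direction, one lateral offset
#' direction, and a fixed marching step.
#'
#' @param probe_origin numeric length-3 physical position (mm) of the first
#'   beam's entry point.
#' @param direction numeric length-3 unit vector shared by all beams.
#' @param lateral numeric length-3 unit vector along which successive beams
#'   are offset.
#' @param beam_count number of beams, `>= 1`.
#' @param beam_spacing lateral distance between adjacent beams (mm).
#' @param samples_per_beam echo samples recorded per beam, `>= 1`.
#' @param step marching step \eqn{\lambda} (mm), `> 0`.
#' @return An object of class `scan_geometry`.
#' @seealso [default_scan_geometry()] to fit one to a volume.
#' @export
scan_geometry <- function(probe_origin, direction, lateral,
                          beam_count, beam_spacing,
                          samples_per_beam, step = 0.3) {
  direction <- as.numeric(direction); lateral <- as.numeric(lateral)
  if (abs(sqrt(sum(direction^2)) - 1) > 1e-9 ||
      abs(sqrt(sum(lateral^2)) - 1) > 1e-9)
    stop("`direction` and `lateral` must be unit vectors", call. = FALSE)
  beam_count <- as.integer(beam_count)
  samples_per_beam <- as.integer(samples_per_beam)
  if (is.na(beam_count) || beam_count < 1L)
    stop("`beam_count` must be >= 1", call. = FALSE)
  if (is.na(samples_per_beam) || samples_per_beam < 1L)
    stop("`samples_per_beam` must be >= 1", call. = FALSE)
  if (step <= 0) stop("`step` must be > 0", call. = FALSE)
  if (beam_spacing < 0) stop("`beam_spacing` must be >= 0", call. = FALSE)
  structure(
    list(probe_origin = as.numeric(probe_origin), direction = direction,
         lateral = lateral, beam_count = beam_count,
         beam_spacing = as.numeric(beam_spacing),
         samples_per_beam = samples_per_beam, step = step),
    class = "scan_geometry"
  )
}

#' Fit a linear scan to a volume
#'
#' Convenience constructor: beams enter the first depth slice (third axis)
#' at mid-height of the second axis, spread evenly across the first axis,
#' and march along `+z` with as many samples as fit inside the volume.
#'
#' @param volume an [attenuation_volume()].
#' @param beam_count number of beams; default one per voxel column.
#' @param step marching step in mm.
#' @return A [scan_geometry()].
#' @export
default_scan_geometry <- function(volume, beam_count = dim(volume$values)[1],
                                  step = 0.3) {
  stopifnot(inherits(volume, "attenuation_volume"))
  d <- dim(volume$values)
  extent_x <- (d[1] - 1) * volume$spacing[1]
  mid_y <- volume$origin[2] + (d[2] - 1) / 2 * volume$spacing[2]
  depth_max <- (d[3] - 1) * volume$spacing[3]
  samples <- max(1L, as.integer(floor(depth_max / step)))
  spacing_lat <- if (beam_count > 1) extent_x / (beam_count - 1) else 0
  scan_geometry(
    probe_origin = c(volume$origin[1], mid_y, volume$origin[3]),
    direction = c(0, 0, 1), lateral = c(1, 0, 0),
    beam_count = beam_count, beam_spacing = spacing_lat,
    samples_per_beam = samples, step = step
  )
}

#' March one ray and record its echo profile
#'
#' Advances a ray through the volume in steps of \eqn{\lambda}, recording
#' at each sample depth the gradient reflection coefficient, the interface
#' transmittance, the incident intensity ratio and the echo amplitude. The
#' incident intensity at sample *k* composites the depth-accumulated
#' attenuation with the transmittance of every interface already crossed:
#' \deqn{I_k = \frac{I(\lambda k)}{I_0} \prod_{j<k} t_j, \qquad
#'       e_k = I_k R_k.}
#'
#' @param volume an [attenuation_volume()].
#' @param ray a [ray()].
#' @param samples number of sample depths (`step`, `2 step`, ...).
#' @param n diffuse exponent for the reflection kernel.
#' @return A tibble of class `echo_profile` with columns `sample`, `depth`
#'   (mm), `reflection`, `transmittance`, `intensity_ratio` and `echo`. If
#'   the ray leaves the volume early the profile is truncated and carries
#'   `attr(, "exited") = TRUE` plus the exit depth.
#' @examples
#' vol <- attenuation_volume(array(1, c(8, 8, 12)), spacing = c(1, 1, 1))
#' march_ray(vol, ray(c(3, 3, 0), c(0, 0, 1), step = 1), samples = 8)
#' @export
march_ray <- function(volume, ray, samples, n = 1) {
  stopifnot(inherits(volume, "attenuation_volume"), inherits(ray, "ray"))
  samples <- as.integer(samples)
  if (is.na(samples) || samples < 1L)
    stop("`samples` must be >= 1", call. = FALSE)

  depths <- ray$step * seq_len(samples)
  mids <- depths - ray$step / 2
  pos_at <- function(s) matrix(ray$origin, length(s), 3, byrow = TRUE) +
    s %o% ray$direction

  # how many whole steps stay inside the volume
  dgrid <- dim(volume$values)
  inside <- function(p) {
    ci <- .continuous_index(volume, p)
    ok <- rep(TRUE, nrow(ci))
    for (ax in 1:3)
      ok <- ok & ci[, ax] >= -1e-9 & ci[, ax] <= dgrid[ax] - 1 + 1e-9
    ok
  }
  ok <- inside(pos_at(depths)) & inside(pos_at(mids))
  m <- if (all(ok)) samples else which(!ok)[1] - 1L
  exited <- m < samples
  if (m == 0L) {
    prof <- tibble::tibble(sample = integer(0), depth = numeric(0),
                           reflection = numeric(0), transmittance = numeric(0),
                           intensity_ratio = numeric(0), echo = numeric(0))
    return(.as_echo_profile(prof, exited, exit_depth = depths[1], ray$step))
  }

  depths <- depths[seq_len(m)]
  mids <- mids[seq_len(m)]
  spts <- pos_at(depths)

  refl <- .reflection_at(volume, spts, ray$direction, n, depths)
  trans <- .transmittance_at(volume, spts, depths)

  g <- .gradient_at(volume, pos_at(mids), mids)
  integrand <- (sqrt(rowSums(g^2)) / (2 * volume$max_delta))^2
  atten <- exp(-cumsum(integrand * ray$step))

  tprod <- cumprod(c(1, trans))[seq_len(m)]  # interfaces strictly above k
  intensity <- atten * tprod
  echo <- intensity * refl

  prof <- tibble::tibble(sample = seq_len(m), depth = depths,
                         reflection = refl, transmittance = trans,
                         intensity_ratio = intensity, echo = echo)
  .as_echo_profile(prof, exited,
                   exit_depth = if (exited) ray$step * (m + 1L) else NA_real_,
                   ray$step)
}

.as_echo_profile <- function(prof, exited, exit_depth, step) {
  attr(prof, "exited") <- exited
  attr(prof, "exit_depth") <- exit_depth
  attr(prof, "step") <- step
  class(prof) <- c("echo_profile", class(prof))
  prof
}

#' Gray-mapping parameters for B-mode rendering
#'
#' Log-compression of echo amplitude to 8-bit gray, plus the acoustic
#' shadow rule: `gray = clamp(round(scale * log(1 + gain * echo)), 0, 255)`,
#' then every sample whose accumulated intensity ratio fell below
#' `shadow_threshold` is overwritten with `gray_floor`.
#'
#' @param gain echo pre-amplification inside the log; `> 0`.
#' @param scale multiplier applied to the log-compressed echo; `> 0`.
#' @param shadow_threshold intensity-ratio threshold in `(0, 1]` below
#'   which a sample is declared shadowed; default 0.92.
#' @param gray_floor gray level in `[0, 255]` written into shadowed
#'   samples; default 50.
#' @param n diffuse exponent of the reflection kernel.
#' @return A list of class `gray_map`.
#' @export
gray_map <- function(gain = 100, scale = 40, shadow_threshold = 0.92,
                     gray_floor = 50, n = 1) {
  if (gain <= 0 || scale <= 0)
    stop("`gain` and `scale` must be > 0", call. = FALSE)
  if (shadow_threshold <= 0 || shadow_threshold > 1)
    stop("`shadow_threshold` must lie in (0, 1]", call. = FALSE)
  if (gray_floor < 0 || gray_floor > 255)
    stop("`gray_floor` must lie in [0, 255]", call. = FALSE)
  structure(list(gain = gain, scale = scale,
                 shadow_threshold = shadow_threshold,
                 gray_floor = as.integer(round(gray_floor)), n = n),
            class = "gray_map")
}

#' Render a B-mode image
#'
#' Marches every beam of a [scan_geometry()] through the volume and maps
#' the echo profiles to an 8-bit image: rows are beams, columns are depth
#' samples. Shadowed samples (accumulated intensity ratio below the
#' threshold) are floored at `gray_floor`; the shadow mask is returned
#' alongside the image so the rule stays testable even where the log
#' mapping lands on the floor value by coincidence.
#'
#' @param volume an [attenuation_volume()].
#' @param geometry a [scan_geometry()]; every beam must fit inside the
#'   volume for all its samples.
#' @param mapping a [gray_map()].
#' @return An object of class `bmode_image` with fields `gray` (integer
#'   matrix, beams x samples, values in `[0, 255]`), `shadow_mask` (logical
#'   matrix), `intensity_ratio` and `echo` (numeric matrices), plus the
#'   mapping and geometry used.
#' @export
render_bmode <- function(volume, geometry, mapping = gray_map()) {
  stopifnot(inherits(volume, "attenuation_volume"),
            inherits(geometry, "scan_geometry"),
            inherits(mapping, "gray_map"))
  nb <- geometry$beam_count
  ns <- geometry$samples_per_beam
  if (nb < 1L || ns < 1L)
    stop("configuration error: empty scan geometry", call. = FALSE)

  gray <- matrix(0L, nb, ns)
  shadow <- matrix(FALSE, nb, ns)
  imat <- matrix(NA_real_, nb, ns)
  emat <- matrix(NA_real_, nb, ns)
  for (b in seq_len(nb)) {
    o <- geometry$probe_origin +
      (b - 1) * geometry$beam_spacing * geometry$lateral
    prof <- march_ray(volume, ray(o, geometry$direction, geometry$step),
                      ns, n = mapping$n)
    if (attr(prof, "exited"))
      stop(sprintf("beam %d exits the volume at depth %.4g mm; shrink the geometry",
                   b, attr(prof, "exit_depth")), call. = FALSE)
    imat[b, ] <- prof$intensity_ratio
    emat[b, ] <- prof$echo
  }
  gray <- matrix(pmin(pmax(as.integer(round(
    mapping$scale * log1p(mapping$gain * emat))), 0L), 255L), nb, ns)
  shadow <- imat < mapping$shadow_threshold
  gray[shadow] <- mapping$gray_floor

  structure(list(gray = gray, shadow_mask = shadow, intensity_ratio = imat,
                 echo = emat, mapping = mapping, geometry = geometry),
            class = "bmode_image")
}

#' @export
print.bmode_image <- function(x, ...) {
  cat(sprintf("<bmode_image> %d beams x %d samples, gray range [%d, %d]\n",
              nrow(x$gray), ncol(x$gray), min(x$gray), max(x$gray)))
  cat(sprintf("  shadow fraction %.3f (threshold %g -> floor %d)\n",
              mean(x$shadow_mask), x$mapping$shadow_threshold,
              x$mapping$gray_floor))
  invisible(x)
}

#' Plot a B-mode image
#'
#' @param object a `bmode_image`.
#' @param ... unused.
#' @return A ggplot: depth down the page, beams across, gray rendered as
#'   brightness.
#' @export
autoplot.bmode_image <- function(object, ...) {
  df <- expand.grid(beam = seq_len(nrow(object$gray)),
                    sample = seq_len(ncol(object$gray)))
  df$gray <- as.vector(object$gray)
  df$depth <- df$sample * object$geometry$step
  ggplot2::ggplot(df, ggplot2::aes(x = .data$beam, y = .data$depth,
                                   fill = .data$gray)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 255)) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "beam", y = "depth (mm)", fill = "gray") +
    ggplot2::theme_minimal()
}

# ---- 8-bit image I/O ---------------------------------------------------

#' Write an 8-bit grayscale image
#'
#' Lossless single-channel output as PNG or binary PGM (P5), chosen by the
#' file extension. Accepts a [render_bmode()] result or a bare integer
#' matrix in `[0, 255]`.
#'
#' @param image a `bmode_image` or integer matrix.
#' @param path output path ending in `.png` or `.pgm`.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  gray <- if (inherits(image, "bmode_image")) image$gray else image
  if (!is.matrix(gray) || any(gray < 0) || any(gray > 255))
    stop("image must be a matrix with values in [0, 255]", call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(gray / 255, path)
  } else if (ext == "pgm") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n255\n", ncol(gray), nrow(gray)), con,
              eos = NULL)
    writeBin(as.raw(as.integer(t(gray))), con)
  } else {
    stop("format error: unsupported image extension '", ext,
         "' (use .png or .pgm)", call. = FALSE)
  }
  invisible(path)
}

#' Read an 8-bit grayscale image
#'
#' @param path a `.png` or `.pgm` file; must be 8-bit single-channel.
#' @return Integer matrix of gray values in `[0, 255]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    hdr <- readBin(path, "raw", n = 26)
    bit_depth <- as.integer(hdr[25])
    color_type <- as.integer(hdr[26])
    if (bit_depth != 8L)
      stop("format error: expected 8-bit PNG, got bit depth ", bit_depth,
           call. = FALSE)
    if (color_type != 0L)
      stop("format error: expected single-channel (grayscale) PNG",
           call. = FALSE)
    m <- png::readPNG(path)
    return(matrix(as.integer(round(m * 255)), nrow(m), ncol(m)))
  }
  if (ext == "pgm") return(.read_pgm(path))
  stop("format error: unsupported image extension '", ext, "'",
       call. = FALSE)
}

.read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # header tokens (magic, width, height, maxval), '#' comments allowed
  tokens <- character(0)
  buf <- character(0)
  while (length(tokens) < 4) {
    ch <- readChar(con, 1, useBytes = TRUE)
    if (length(ch) == 0) stop("format error: truncated PGM header",
                              call. = FALSE)
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1, useBytes = TRUE)
        if (length(ch) == 0 || ch == "\n") break
      }
      ch <- " "
    }
    if (grepl("[[:space:]]", ch)) {
      if (length(buf)) { tokens <- c(tokens, paste(buf, collapse = ""));
                         buf <- character(0) }
    } else buf <- c(buf, ch)
  }
  magic <- tokens[1]
  w <- as.integer(tokens[2]); h <- as.integer(tokens[3])
  maxval <- as.integer(tokens[4])
  if (!magic %in% c("P2", "P5"))
    stop("format error: not a PGM file (magic '", magic, "')", call. = FALSE)
  if (is.na(maxval) || maxval > 255)
    stop("format error: expected 8-bit PGM, got maxval ", maxval,
         call. = FALSE)
  vals <- if (magic == "P5") {
    as.integer(readBin(con, "raw", n = w * h))
  } else {
    scan(con, what = integer(), n = w * h, quiet = TRUE)
  }
  if (length(vals) != w * h)
    stop("format error: truncated PGM pixel data", call. = FALSE)
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}
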