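#' PCR amplification model
#'
#' Idealized exponential PCR: starting from `x0` template molecules, each
#' cycle multiplies the product count by `1 + E`, where the amplification
#' efficiency `E` lies in `[0, 1]` (E = 1 is perfect doubling). Real
#' reactions leave the exponential regime after a limited number of cycles
#' — generally 20 to 30 — so the model applies a hard plateau: beyond
#' `plateau_cycle` no further amplification occurs.
#'
#' @param x0 initial template molecule count, `> 0`.
#' @param efficiency per-cycle amplification efficiency `E` in `[0, 1]`.
#' @param plateau_cycle cycle beyond which amplification stops; default 30.
#' @return An object of class `amplification_model`.
#' @examples
#' m <- amplification_model(x0 = 1, efficiency = 1)
#' amplify(m, 10)  # 2^10 = 1024
#' @export
amplification_model <- function(x0, efficiency, plateau_cycle = 30L) {
  if (!is.numeric(x0) || length(x0) != 1L || !is.finite(x0) || x0 <= 0)
    stop("`x0` must be a single value > 0", call. = FALSE)
  if (!is.numeric(efficiency) || length(efficiency) != 1L ||
      !is.finite(efficiency) || efficiency < 0 || efficiency > 1)
    stop("`efficiency` must lie in [0, 1]", call. = FALSE)
  plateau_cycle <- as.integer(plateau_cycle)
  if (is.na(plateau_cycle) || plateau_cycle < 1L)
    stop("`plateau_cycle` must be >= 1", call. = FALSE)
  structure(list(x0 = x0, efficiency = efficiency,
                 plateau_cycle = plateau_cycle),
            class = "amplification_model")
}

#' Expected PCR product after n cycles
#'
#' \eqn{Y_n = X (1 + E)^{\min(n, n_{plateau})}}: exponential growth with
#' the per-cycle recursion \eqn{Y_n = Y_{n-1}(1+E)} below the plateau,
#' constant beyond it.
#'
#' @param model an [amplification_model()].
#' @param n cycle count(s), non-negative integers. Vectorized.
#' @return Expected product molecule count(s).
#' @export
amplify <- function(model, n) {
  stopifnot(inherits(model, "amplification_model"))
  if (any(!is.finite(n)) || any(n < 0) || any(n != floor(n)))
    stop("`n` must be non-negative integer cycle counts", call. = FALSE)
  # repeated multiplication (not pow) so the per-cycle recursion
  # Y_n = Y_{n-1} * (1 + E) holds exactly in floating point
  k <- pmin(n, model$plateau_cycle)
  b <- 1 + model$efficiency
  ys <- Reduce(function(y, i) y * b, seq_len(max(k, 0)), init = model$x0,
               accumulate = TRUE)
  ys[k + 1]
}

#' Relative expression by the 2^-ddCt method
#'
#' Standard relative quantification from threshold cycles, assuming
#' perfect doubling per cycle:
#' \deqn{2^{-((Ct_{target,case} - Ct_{ref,case}) -
#'           (Ct_{target,control} - Ct_{ref,control}))}}
#'
#' @param ct_target_case,ct_ref_case threshold cycles of the target and
#'   reference gene in the case sample.
#' @param ct_target_control,ct_ref_control the same in the control sample.
#' @return Fold change relative to control; 1 when the double difference
#'   is zero. Vectorized.
#' @examples
#' fold_change(24, 20, 22, 20)  # ddCt = 2 -> 0.25
#' @export
fold_change <- function(ct_target_case, ct_ref_case,
                        ct_target_control, ct_ref_control) {
  cts <- c(ct_target_case, ct_ref_case, ct_target_control, ct_ref_control)
  if (any(!is.finite(cts)))
    stop("all Ct values must be finite", call. = FALSE)
  ddct <- (ct_target_case - ct_ref_case) -
    (ct_target_control - ct_ref_control)
  2^(-ddct)
}

#' ELISA standard series
#'
#' A serial-dilution standard curve: concentrations from the top standard
#' down by a constant dilution factor, terminated by a blank at 0. For
#' plates whose standards do not follow a single geometric dilution, pass
#' the concentrations explicitly via `concentrations` (they must be
#' strictly decreasing, ending in the blank 0).
#'
#' @param analyte analyte name (e.g. `"TNF-alpha"`).
#' @param top top standard concentration (pg/mL), `> 0`.
#' @param dilution_factor ratio between adjacent standards, `> 1`;
#'   default 2 (two-fold serial dilution).
#' @param levels number of non-blank standards, `>= 1`; default 7.
#' @param concentrations optional explicit concentration vector overriding
#'   the geometric construction.
#' @return An object of class `standard_series`; `tidy()` turns it into a
#'   tibble of levels and concentrations.
#' @examples
#' standard_series("TNF-alpha", top = 5000)
#' standard_series("NF-kB",
#'   concentrations = c(5000, 2500, 1000, 500, 200, 100, 50, 0))
#' @export
standard_series <- function(analyte, top = NULL, dilution_factor = 2,
                            levels = 7L, concentrations = NULL) {
  if (is.null(concentrations)) {
    if (is.null(top) || !is.finite(top) || top <= 0)
      stop("`top` must be > 0", call. = FALSE)
    if (!is.finite(dilution_factor) || dilution_factor <= 1)
      stop("configuration error: `dilution_factor` must be > 1",
           call. = FALSE)
    levels <- as.integer(levels)
    if (is.na(levels) || levels < 1L)
      stop("`levels` must be >= 1", call. = FALSE)
    concentrations <- c(top / dilution_factor^(seq_len(levels) - 1), 0)
  } else {
    concentrations <- as.numeric(concentrations)
    if (any(!is.finite(concentrations)) || any(concentrations < 0))
      stop("concentrations must be finite and >= 0", call. = FALSE)
    k <- length(concentrations)
    if (k < 2L || concentrations[k] != 0)
      stop("explicit concentrations must end in a blank 0", call. = FALSE)
    if (any(diff(concentrations[-k]) >= 0) || concentrations[k - 1] <= 0)
      stop("non-blank concentrations must be strictly decreasing",
           call. = FALSE)
  }
  structure(list(analyte = analyte, concentrations = concentrations),
            class = "standard_series")
}

#' @export
print.standard_series <- function(x, ...) {
  cat(sprintf("<standard_series> %s: %s pg/mL\n", x$analyte,
              paste(format(x$concentrations, trim = TRUE), collapse = ", ")))
  invisible(x)
}

#' @rdname standard_series
#' @param x a `standard_series`.
#' @param ... unused.
#' @export
tidy.standard_series <- function(x, ...) {
  tibble::tibble(analyte = x$analyte,
                 level = seq_along(x$concentrations),
                 concentration = x$concentrations)
}

#' Calibrate sample responses against a standard curve
#'
#' Interpolates sample signals on the measured standard responses:
#' log-linear between bracketing standards (linear in log-signal versus
#' log-concentration, so a signal at the geometric mean of two standards'
#' responses maps to the geometric mean of their concentrations). A signal
#' equal to a standard's own response returns exactly that standard's
#' concentration. Signals below the blank's response are floored at 0 and
#' flagged `below_blank`; signals between the blank and the lowest
#' standard interpolate linearly on that segment (`below_curve`); signals
#' above the top standard are out of range (`above_range`, concentration
#' `NA`).
#'
#' @param series a [standard_series()].
#' @param standard_responses measured signal per standard, same length and
#'   order as `series$concentrations` (blank last); must be strictly
#'   monotone over the non-blank standards.
#' @param sample_response signal(s) to calibrate. Vectorized.
#' @return A tibble with columns `response`, `concentration`, `flag`
#'   (`"ok"`, `"below_blank"`, `"below_curve"` or `"above_range"`).
#' @export
calibrate <- function(series, standard_responses, sample_response) {
  stopifnot(inherits(series, "standard_series"))
  conc <- series$concentrations
  resp <- as.numeric(standard_responses)
  if (length(resp) != length(conc))
    stop("`standard_responses` must match the series length (blank last)",
         call. = FALSE)
  if (any(!is.finite(resp)))
    stop("standard responses must be finite", call. = FALSE)

  k <- length(conc)                 # conc is decreasing, blank last
  nb_resp <- resp[-k]               # non-blank responses, top standard first
  dr <- diff(nb_resp)
  if (any(dr == 0) || (any(dr > 0) && any(dr < 0))) {
    bad <- which(dr == 0 | sign(dr) != sign(dr[1]))[1]
    stop(sprintf(
      "calibration error: standard responses not strictly monotone between levels %d and %d",
      bad, bad + 1), call. = FALSE)
  }
  increasing <- dr[1] < 0  # responses increase with concentration

  # reorder to ascending response; the blank sits at one end
  ord <- if (increasing) k:1 else 1:k
  conc_a <- conc[ord]
  resp_a <- resp[ord]
  m <- length(resp_a)
  if (any(diff(resp_a) <= 0))
    stop("calibration error: blank response is not on the monotone side of the curve",
         call. = FALSE)
  blank_low <- increasing  # blank at the low-response end of the curve?

  one <- function(s) {
    if (!is.finite(s)) return(c(NA_real_, NA))
    if (s < resp_a[1])
      return(if (blank_low) c(0, 1L) else c(NA_real_, 3L))
    if (s > resp_a[m])
      return(if (blank_low) c(NA_real_, 3L) else c(0, 1L))
    eq <- which(resp_a == s)  # node identity: return that standard exactly
    if (length(eq))
      return(c(conc_a[eq[1]], if (conc_a[eq[1]] == 0) 2L else 0L))
    j <- findInterval(s, resp_a)
    lo <- j; hi <- j + 1L
    if (conc_a[lo] == 0 || conc_a[hi] == 0) {
      # blank segment: interpolate linearly in response toward conc 0
      w <- (s - resp_a[lo]) / (resp_a[hi] - resp_a[lo])
      return(c((1 - w) * conc_a[lo] + w * conc_a[hi], 2L))
    }
    # log-linear: log-signal vs log-concentration (linear fallback when a
    # response is non-positive and its log is undefined)
    if (resp_a[lo] > 0 && s > 0)
      w <- (log(s) - log(resp_a[lo])) / (log(resp_a[hi]) - log(resp_a[lo]))
    else
      w <- (s - resp_a[lo]) / (resp_a[hi] - resp_a[lo])
    c(exp((1 - w) * log(conc_a[lo]) + w * log(conc_a[hi])), 0L)
  }
  res <- t(vapply(as.numeric(sample_response), one, numeric(2)))
  flags <- c("ok", "below_blank", "below_curve", "above_range")
  tibble::tibble(response = as.numeric(sample_response),
                 concentration = res[, 1],
                 flag = flags[res[, 2] + 1L])
}
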