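#' Two-group sample
#'
#' A pair of measurement vectors to be compared (e.g. patients versus
#' healthy controls for one analyte).
#'
#' @param group_a,group_b numeric vectors, each nonempty and finite.
#' @param label_a,label_b group names.
#' @param units measurement units (string), for printing only.
#' @return An object of class `two_group_sample`.
#' @export
two_group_sample <- function(group_a, group_b, label_a = "A", label_b = "B",
                             units = "") {
  group_a <- as.numeric(group_a); group_b <- as.numeric(group_b)
  if (length(group_a) == 0 || length(group_b) == 0)
    stop("both groups must be nonempty", call. = FALSE)
  if (any(!is.finite(group_a)) || any(!is.finite(group_b)))
    stop("all measurements must be finite", call. = FALSE)
  structure(list(group_a = group_a, group_b = group_b,
                 label_a = label_a, label_b = label_b, units = units),
            class = "two_group_sample")
}

#' @export
print.two_group_sample <- function(x, ...) {
  cat(sprintf("<two_group_sample> %s (n=%d) vs %s (n=%d)%s\n",
              x$label_a, length(x$group_a), x$label_b, length(x$group_b),
              if (nzchar(x$units)) paste0(", ", x$units) else ""))
  invisible(x)
}

#' Welch two-sample comparison
#'
#' The unequal-variance t statistic
#' \deqn{t = \frac{\bar{x}_a - \bar{x}_b}
#'                {\sqrt{s_a^2/n_a + s_b^2/n_b}}}
#' with Welch-Satterthwaite degrees of freedom and a two-sided p-value
#' from the t distribution. Implemented directly from the formulas;
#' `stats::t.test(var.equal = FALSE)` is used only as a cross-check in the
#' test suite. Two constant, equal groups return `t = 0`, `p = 1` rather
#' than 0/0.
#'
#' @param sample a [two_group_sample()], or the first group as a numeric
#'   vector (then `group_b` must be given).
#' @param group_b second group when `sample` is a bare vector.
#' @return A one-row tibble with columns `statistic` (t), `parameter`
#'   (Welch df), `p.value`, `estimate` (mean difference a - b), `mean_a`,
#'   `mean_b`, `n_a`, `n_b`.
#' @examples
#' welch_test(c(1, 2, 3, 4), c(2, 4, 6, 8))
#' @export
welch_test <- function(sample, group_b = NULL) {
  if (inherits(sample, "two_group_sample")) {
    a <- sample$group_a; b <- sample$group_b
  } else {
    if (is.null(group_b))
      stop("supply a two_group_sample or two numeric vectors", call. = FALSE)
    a <- as.numeric(sample); b <- as.numeric(group_b)
  }
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2)
    stop("each group needs at least 2 values", call. = FALSE)
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("all measurements must be finite", call. = FALSE)

  va <- stats::var(a) / na
  vb <- stats::var(b) / nb
  diff <- mean(a) - mean(b)
  if (va + vb == 0) {
    tstat <- 0; df <- na + nb - 2; p <- 1
    if (diff != 0)
      stop("zero variance in both groups with unequal means", call. = FALSE)
  } else {
    tstat <- diff / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
    p <- 2 * stats::pt(-abs(tstat), df)
  }
  tibble::tibble(statistic = tstat, parameter = df, p.value = p,
                 estimate = diff, mean_a = mean(a), mean_b = mean(b),
                 n_a = na, n_b = nb)
}

#' ROC analysis with AUC, Hanley-McNeil SE and Youden cut-off
#'
#' Builds the empirical ROC of a continuous marker separating cases from
#' controls. The AUC is the Mann-Whitney pair-counting probability (ties
#' count 1/2); its standard error uses the Hanley-McNeil formula; the 95%
#' CI is `auc +/- 1.96 se`, truncated to `[0, 1]`. The reported cut-off is
#' the candidate threshold (midpoints between adjacent distinct pooled
#' values, plus infinite sentinels) maximizing the Youden index
#' (sensitivity + specificity - 1); ties are broken toward higher
#' specificity, then toward the more conservative (higher) threshold.
#'
#' Sensitivity is defined on the cases. `direction = "higher"` means cases
#' are expected to take larger marker values (a case is called when the
#' value exceeds the cut-off); use `"lower"` for markers depressed in
#' cases, e.g. strain indices that become more negative with disease.
#'
#' @param cases,controls numeric vectors of marker values, nonempty.
#' @param direction `"higher"` (default) or `"lower"`: which side of the
#'   cut-off is called a case.
#' @return An object of class `roc_result` with fields `auc`, `se`,
#'   `ci95`, `cutoff`, `sensitivity`, `specificity`, `direction`,
#'   `n_cases`, `n_controls` and the full `curve` (a tibble of candidate
#'   thresholds with their sensitivity/specificity). `tidy()` returns the
#'   curve, `glance()` the one-row summary, `autoplot()` the ROC plot.
#' @examples
#' r <- roc_analysis(c(3, 4, 5, 6), c(1, 2, 3, 4))
#' glance(r)
#' @export
roc_analysis <- function(cases, controls, direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  cases <- as.numeric(cases); controls <- as.numeric(controls)
  if (length(cases) == 0 || length(controls) == 0)
    stop("both groups must be nonempty", call. = FALSE)
  if (any(!is.finite(cases)) || any(!is.finite(controls)))
    stop("all marker values must be finite", call. = FALSE)

  sgn <- if (direction == "higher") 1 else -1
  x <- sgn * cases; y <- sgn * controls
  n1 <- length(x); n0 <- length(y)

  # Mann-Whitney AUC via midranks (pair counting with ties = 1/2)
  r <- rank(c(x, y), ties.method = "average")
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  # Hanley-McNeil standard error
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
              (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  ci95 <- pmin(pmax(auc + c(-1.96, 1.96) * se, 0), 1)

  # candidate thresholds: midpoints between adjacent distinct pooled
  # values, with infinite sentinels
  u <- sort(unique(c(x, y)))
  cand <- if (length(u) > 1) (u[-length(u)] + u[-1]) / 2 else numeric(0)
  cand <- c(-Inf, cand, Inf)
  sens <- vapply(cand, function(cc) mean(x > cc), numeric(1))
  spec <- vapply(cand, function(cc) mean(y <= cc), numeric(1))
  youden <- sens + spec - 1
  best <- which(youden == max(youden))
  best <- best[spec[best] == max(spec[best])]
  best <- best[length(best)]  # most conservative (largest) threshold

  curve <- tibble::tibble(threshold = sgn * cand,
                          sensitivity = sens, specificity = spec,
                          youden = youden)
  structure(
    list(auc = auc, se = se, ci95 = ci95, cutoff = sgn * cand[best],
         sensitivity = sens[best], specificity = spec[best],
         direction = direction, n_cases = n1, n_controls = n0,
         curve = curve),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (SE %.3f, 95%% CI %.3f-%.3f)\n",
              x$auc, x$se, x$ci95[1], x$ci95[2]))
  cat(sprintf("  cut-off %.4g (%s in cases): Se %.0f%%, Sp %.0f%% [n = %d/%d]\n",
              x$cutoff, x$direction, 100 * x$sensitivity,
              100 * x$specificity, x$n_cases, x$n_controls))
  invisible(x)
}

#' @rdname roc_analysis
#' @param x a `roc_result`.
#' @param ... unused.
#' @export
tidy.roc_result <- function(x, ...) x$curve

#' @rdname roc_analysis
#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, se = x$se,
                 ci_low = x$ci95[1], ci_high = x$ci95[2],
                 cutoff = x$cutoff, sensitivity = x$sensitivity,
                 specificity = x$specificity,
                 n_cases = x$n_cases, n_controls = x$n_controls)
}

#' @rdname roc_analysis
#' @param object a `roc_result`.
#' @export
autoplot.roc_result <- function(object, ...) {
  df <- object$curve[order(1 - object$curve$specificity,
                           object$curve$sensitivity), ]
  ggplot2::ggplot(df, ggplot2::aes(x = 1 - .data$specificity,
                                   y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::annotate("point", x = 1 - object$specificity,
                      y = object$sensitivity, colour = "red") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

# frozen checksum of the bundled per-subject surfactant-protein table
.SP_FIXTURE_MD5 <- "10976e4546f03ce5dc8d5e1510d054b1"

#' Bundled surfactant-protein measurements
#'
#' Per-subject SP-A and SP-D concentrations (ng/mL) for 50 stable-stage
#' COPD patients and 50 healthy controls, shipped as a plain-text CSV and
#' integrity-checked against a frozen checksum on every load. This is the
#' package's worked fixture for [roc_analysis()] and [welch_test()].
#'
#' @param path optional override of the bundled CSV (for testing).
#' @return A named list of two [two_group_sample()] objects, `SP-A` and
#'   `SP-D`, each with `group_a` = Con (controls) and `group_b` = COPD
#'   (cases).
#' @examples
#' fx <- load_sp_fixture()
#' length(fx[["SP-D"]]$group_b)  # 50 patients
#' @export
load_sp_fixture <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "sp_table5.csv", package = "sonosim",
                        mustWork = TRUE)
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, .SP_FIXTURE_MD5))
    stop("data-integrity error: fixture checksum mismatch for ", path,
         call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(c("SP-A", "SP-D"), function(an) {
    con <- df$value[df$analyte == an & df$group == "Con"]
    copd <- df$value[df$analyte == an & df$group == "COPD"]
    if (length(con) != 50L || length(copd) != 50L)
      stop("data-integrity error: expected 50 records per group for ", an,
           call. = FALSE)
    two_group_sample(con, copd, label_a = "Con", label_b = "COPD",
                     units = "ng/mL")
  })
  names(out) <- c("SP-A", "SP-D")
  out
}
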