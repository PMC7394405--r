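# Net relative regrowth, the clipping-experiment calibration line, and its
# inversion to per-camp grazing frequency.

#' Net relative regrowth of a sward height series
#'
#' ln(final height) - ln(initial height) over the observation period; may be
#' negative when grazing outpaces growth.
#'
#' @param series Data frame with `day` and `height_cm` for one sward, or a
#'   numeric vector of heights in time order.
#' @return Net relative regrowth (dimensionless, log scale).
#' @examples
#' relative_regrowth(c(10, 12, 14.6))   # ln(1.46)
#' @export
relative_regrowth <- function(series) {
  if (is.data.frame(series)) {
    stopifnot(all(c("day", "height_cm") %in% names(series)))
    series <- series$height_cm[order(series$day)]
  }
  h <- as.numeric(series)
  if (length(h) < 2) stop("need at least 2 time points", call. = FALSE)
  if (any(!is.finite(h)) || any(h <= 0)) {
    stop("sward heights must be positive", call. = FALSE)
  }
  log(h[length(h)]) - log(h[1])
}

#' Back-transform relative regrowth to percentage growth
#'
#' @param r Net relative regrowth (log scale).
#' @return Percentage growth, 100 * (exp(r) - 1).
#' @examples
#' pct_growth(log(1.56))   # +56
#' pct_growth(log(0.80))   # -20
#' @export
pct_growth <- function(r) {
  100 * (exp(r) - 1)
}

#' Construct a defoliation-regrowth calibration line
#'
#' @param slope Regrowth units per defoliation event (expected negative).
#' @param intercept Regrowth at zero events (log scale).
#' @param r_squared Coefficient of determination of the fit, in \[0, 1\].
#' @param n_points Number of points the line was fitted to.
#' @return An object of class `calibration_line`.
#' @export
calibration_line <- function(slope, intercept, r_squared = NA_real_,
                             n_points = NA_integer_) {
  stopifnot(is.numeric(slope), is.numeric(intercept))
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1)) {
    stop("r_squared must be in [0, 1]", call. = FALSE)
  }
  structure(
    list(slope = slope, intercept = intercept, r_squared = r_squared,
         n_points = n_points),
    class = "calibration_line"
  )
}

#' @export
print.calibration_line <- function(x, ...) {
  cat(sprintf("Calibration line: regrowth = %.4f + (%.4f) x events  (r^2 = %s, n = %s)\n",
              x$intercept, x$slope,
              ifelse(is.na(x$r_squared), "NA", sprintf("%.3f", x$r_squared)),
              x$n_points))
  invisible(x)
}

#' Fit the clipping-experiment calibration line
#'
#' Ordinary least squares of net relative regrowth on the number of
#' defoliation events. The unclipped (zero-event) treatment is excluded by the
#' caller: the line describes regrowth of swards that were actually grazed.
#'
#' @param clip_count Number of defoliation events per sward.
#' @param regrowth Net relative regrowth per sward (same length).
#' @return A [calibration_line()].
#' @export
fit_calibration <- function(clip_count, regrowth) {
  stopifnot(length(clip_count) == length(regrowth))
  if (length(clip_count) < 2) stop("need at least 2 points", call. = FALSE)
  if (length(unique(clip_count)) < 2) {
    stop("slope undefined: all clip counts identical", call. = FALSE)
  }
  fit <- stats::lm(regrowth ~ clip_count)
  # direct r^2 (summary.lm warns on exact fits, which are legitimate here)
  ss_tot <- sum((regrowth - mean(regrowth))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::resid(fit)^2) / ss_tot else 1
  calibration_line(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = r2,
    n_points = length(clip_count)
  )
}

#' Invert the calibration line to estimate grazing frequency
#'
#' Solves the calibration line for the event count x at an observed net
#' relative regrowth: x = (regrowth - intercept) / slope. The continuous
#' solution is always returned alongside the nearest-integer estimate
#' (ties to even, the R rounding convention). A negative solution is returned
#' but flagged, since it falls outside the calibrated domain.
#'
#' @param line A [calibration_line()].
#' @param regrowth Net relative regrowth value(s) observed in a camp.
#' @return Tibble with `regrowth`, `x_continuous`, `x_rounded`,
#'   `out_of_domain`.
#' @examples
#' line <- calibration_line(slope = -0.0606, intercept = 0.6502)
#' invert_grazing_frequency(line, log(c(1.46, 1.56, 0.80)))
#' @export
invert_grazing_frequency <- function(line, regrowth) {
  stopifnot(inherits(line, "calibration_line"))
  if (line$slope == 0) stop("slope is zero: inversion undefined", call. = FALSE)
  x <- (regrowth - line$intercept) / line$slope
  tibble::tibble(
    regrowth = regrowth,
    x_continuous = x,
    x_rounded = as.integer(round(x)),
    out_of_domain = x < 0
  )
}

#' Shift regrowth values to be non-negative
#'
#' Gamma-family group comparisons require positive responses; grazed-sward
#' regrowth can be negative. When the minimum is negative its absolute value
#' is added to every value; otherwise the data are returned unchanged. The
#' constant used is returned so the transform is invertible.
#'
#' @param x Numeric vector of regrowth values.
#' @return List with `values` (shifted) and `constant` (the shift applied).
#' @examples
#' shift_transform(c(-0.3, 0.1))   # values 0.0, 0.4; constant 0.3
#' @export
shift_transform <- function(x) {
  if (length(x) == 0) stop("empty input", call. = FALSE)
  stopifnot(is.numeric(x), all(is.finite(x)))
  const <- if (min(x) < 0) -min(x) else 0
  list(values = x + const, constant = const)
}
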