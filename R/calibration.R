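#' Weighted second-order calibration
#'
#' Fits the quantification model `y = a*x^2 + b*x + c` relating the
#' analyte/internal-standard response ratio `y` to the nominal concentration
#' `x`, by weighted least squares. A second-order curve accommodates the
#' wide (nearly three decades) calibration range; the default `1/x` weight
#' reflects the roughly constant relative (not absolute) error of MRM peak
#' heights. The origin is excluded: all calibrators must have `x > 0`.
#'
#' The coefficient of determination is computed on the weighted scale,
#' `R2 = 1 - SSE_w/SST_w` with the weighted mean in the total sum of
#' squares; the unweighted value is reported alongside. Monotonicity of the
#' fitted curve over the calibration range is verified (the derivative
#' `2*a*x + b` is linear in `x`, so checking the endpoints suffices); a
#' non-monotone fit is flagged and signalled as a warning, and
#' quantification remains permitted on the monotone branch.
#'
#' @param x Nominal concentrations of the calibrators (ng/mL or ng/g), all
#'   positive, at least three distinct levels.
#' @param y Response ratios (analyte peak height / IS peak height), >= 0.
#' @param weighting `"1/x"` (default), `"1/x^2"`, or `"none"`.
#' @param range Calibration range `(low, high)`; defaults to `range(x)`.
#' @param analyte Analyte identifier carried along for reporting.
#' @param loq Limit of quantification; defaults to the lowest calibrator.
#' @return An object of class `calibration_curve` with elements
#'   `coefficients` (named `a`, `b`, `c`), `weighting`, `range`,
#'   `r_squared` (weighted scale), `r_squared_unweighted`, `loq`,
#'   `monotone`, `n_levels`, `n_points`, `analyte`.
#' @seealso [back_calculate()], [assess_loq()]
#' @export
fit_calibration <- function(x, y, weighting = c("1/x", "1/x^2", "none"),
                            range = NULL, analyte = NA_character_, loq = NULL) {
  weighting <- match.arg(weighting)
  tq_check(is.numeric(x) && is.numeric(y) && length(x) == length(y),
           "x and y must be numeric vectors of equal length",
           class = "tq_invalid_input")
  tq_check(all(is.finite(x)) && all(is.finite(y)),
           "calibration points must be finite", class = "tq_invalid_input")
  if (any(x <= 0)) {
    tq_error("calibrator concentrations must be positive (origin is excluded)",
             class = "tq_invalid_input")
  }
  tq_check(all(y >= 0), "response ratios must be non-negative",
           class = "tq_invalid_input")
  n_levels <- length(unique(x))
  if (n_levels < 3L) {
    tq_error(sprintf("calibration needs >= 3 distinct concentration levels, got %d",
                     n_levels), class = "tq_insufficient_calibration")
  }
  w <- switch(weighting, "1/x" = 1 / x, "1/x^2" = 1 / x^2, "none" = rep(1, length(x)))
  fit <- stats::lm(y ~ x + I(x^2), weights = w)
  cf <- stats::coef(fit)
  coefficients <- c(a = unname(cf[["I(x^2)"]]), b = unname(cf[["x"]]),
                    c = unname(cf[["(Intercept)"]]))
  coefficients[is.na(coefficients)] <- 0

  fitted_y <- coefficients["a"] * x^2 + coefficients["b"] * x + coefficients["c"]
  r2 <- function(wt) {
    sse <- sum(wt * (y - fitted_y)^2)
    ybar <- sum(wt * y) / sum(wt)
    sst <- sum(wt * (y - ybar)^2)
    if (sst <= 0) NA_real_ else 1 - sse / sst
  }
  rng <- if (is.null(range)) base::range(x) else as.numeric(range)
  deriv_ends <- 2 * coefficients["a"] * rng + coefficients["b"]
  monotone <- all(deriv_ends > 0)
  curve <- structure(
    list(analyte = analyte,
         coefficients = coefficients,
         weighting = weighting,
         range = rng,
         r_squared = r2(w),
         r_squared_unweighted = r2(rep(1, length(x))),
         loq = loq %||% min(x),
         monotone = monotone,
         n_levels = n_levels,
         n_points = length(x)),
    class = "calibration_curve")
  if (!monotone) {
    tq_warn(sprintf(
      "calibration curve%s is not strictly increasing over [%g, %g]; quantification restricted to the monotone branch",
      if (is.na(analyte)) "" else paste0(" for ", analyte), rng[1], rng[2]),
      class = "tq_non_monotone")
  }
  curve
}

#' @export
print.calibration_curve <- function(x, ...) {
  cf <- x$coefficients
  cat(sprintf("<calibration_curve>%s y = %.4g*x^2 + %.4g*x + %.4g\n",
              if (is.na(x$analyte)) "" else paste0(" ", x$analyte),
              cf["a"], cf["b"], cf["c"]))
  cat(sprintf("  weighting %s; range [%g, %g]; LOQ %g; R2(w) %.5f; R2 %.5f%s\n",
              x$weighting, x$range[1], x$range[2], x$loq,
              x$r_squared, x$r_squared_unweighted,
              if (x$monotone) "" else "; NON-MONOTONE"))
  invisible(x)
}

#' @param object A `calibration_curve`.
#' @param x Concentrations at which to evaluate the curve.
#' @param ... Unused.
#' @rdname fit_calibration
#' @export
predict.calibration_curve <- function(object, x, ...) {
  cf <- object$coefficients
  unname(cf[["a"]] * x^2 + cf[["b"]] * x + cf[["c"]])
}

#' Back-calculate a concentration from a response ratio
#'
#' Inverts the fitted quadratic: returns the `x` solving
#' `a*x^2 + b*x + c = response`. Root selection policy: the real root inside
#' `[0, 1.2 * high]` (a 20% head-room above the top calibrator; beyond that
#' the sample signals "above calibration range" rather than extrapolating);
#' when both roots qualify, the one on the monotone branch containing the
#' calibration range. A result below the lowest calibrator is returned
#' as-is — below-LOQ annotation is the caller's responsibility
#' (see [quantify_sample()]).
#'
#' @param curve A `calibration_curve`.
#' @param response Non-negative response ratio(s).
#' @return Concentration(s), same units as the calibrators.
#'   Signals a condition of class `tq_out_of_range` (with fields `response`
#'   and `direction`, `"above"` or `"below"`) when no admissible root exists.
#' @export
back_calculate <- function(curve, response) {
  tq_check(inherits(curve, "calibration_curve"), "curve must be a calibration_curve",
           class = "tq_usage_error")
  tq_check(is.numeric(response) && all(response >= 0),
           "response must be non-negative", class = "tq_invalid_input")
  vapply(response, back_calculate_one, numeric(1), curve = curve)
}

back_calculate_one <- function(curve, response) {
  cf <- curve$coefficients
  a <- cf[["a"]]; b <- cf[["b"]]; cc <- cf[["c"]]
  ceiling_x <- 1.2 * curve$range[2]

  out_of_range <- function(direction) {
    stop(errorCondition(
      sprintf("response %.6g has no admissible root in [0, %.4g] (%s calibration range)",
              response, ceiling_x, direction),
      response = response, direction = direction,
      class = c("tq_out_of_range", "toxiquant_error")))
  }

  if (a == 0) {
    if (b == 0) out_of_range(if (response > cc) "above" else "below")
    x <- (response - cc) / b
    if (x < 0) out_of_range(if (b > 0) "below" else "above")
    if (x > ceiling_x) out_of_range(if (b > 0) "above" else "below")
    return(x)
  }

  disc <- b^2 - 4 * a * (cc - response)
  vertex <- -b / (2 * a)
  if (disc < 0) {
    # no real root: response lies beyond the parabola's extremum
    out_of_range(if (a > 0) "below" else "above")
  }
  roots <- sort((-b + c(-1, 1) * sqrt(disc)) / (2 * a))
  ok <- roots >= 0 & roots <= ceiling_x
  if (!any(ok)) {
    # direction from the attainable response values on [0, ceiling]
    xs <- c(0, ceiling_x, if (vertex > 0 && vertex < ceiling_x) vertex)
    ys <- a * xs^2 + b * xs + cc
    out_of_range(if (response > max(ys)) "above" else "below")
  }
  if (sum(ok) == 1L) return(roots[ok])
  # both roots admissible: keep the one on the branch holding the range
  mid <- mean(curve$range)
  on_right <- mid >= vertex
  if (on_right) max(roots[ok]) else min(roots[ok])
}

#' Limit-of-quantification decision
#'
#' The LOQ is set at the level of the lowest calibrator, provided the
#' signal-to-noise ratio there is at least 10. S/N is defined as the peak
#' height divided by the standard deviation of a peak-free baseline
#' segment.
#'
#' @param lowest_calibrator Concentration of the lowest calibrator.
#' @param peak_height Quantifier peak height at that level.
#' @param baseline_noise_sd Standard deviation of the baseline, positive.
#' @param sn_threshold Acceptance threshold, default 10.
#' @return An object of class `loq_decision` with `loq` (NA when rejected),
#'   `signal_to_noise`, `accepted`.
#' @export
assess_loq <- function(lowest_calibrator, peak_height, baseline_noise_sd,
                       sn_threshold = 10) {
  if (!is.numeric(baseline_noise_sd) || baseline_noise_sd <= 0) {
    tq_error("baseline noise SD must be positive", class = "tq_invalid_input")
  }
  tq_check(is.numeric(peak_height) && peak_height >= 0 &&
             is.numeric(lowest_calibrator) && lowest_calibrator > 0,
           "peak height must be >= 0 and the lowest calibrator > 0",
           class = "tq_invalid_input")
  sn <- peak_height / baseline_noise_sd
  accepted <- sn >= sn_threshold
  structure(list(loq = if (accepted) lowest_calibrator else NA_real_,
                 signal_to_noise = sn, accepted = accepted,
                 sn_threshold = sn_threshold),
            class = "loq_decision")
}

#' @export
print.loq_decision <- function(x, ...) {
  cat(sprintf("<loq_decision> S/N %.2f (threshold %g): %s%s\n",
              x$signal_to_noise, x$sn_threshold,
              if (x$accepted) "accepted" else "rejected",
              if (x$accepted) sprintf(", LOQ = %g", x$loq) else ""))
  invisible(x)
}

#' Tabulate fitted calibration curves
#'
#' One row per analyte: coefficients, weighted and unweighted R-squared,
#' LOQ and range — the audit record serialized by the pipeline.
#'
#' @param curves List of `calibration_curve` objects.
#' @return A data frame.
#' @export
calibration_report <- function(curves) {
  if (inherits(curves, "calibration_curve")) curves <- list(curves)
  do.call(rbind, lapply(curves, function(cu) {
    data.frame(analyte = cu$analyte, a = cu$coefficients[["a"]],
               b = cu$coefficients[["b"]], c = cu$coefficients[["c"]],
               r_squared = cu$r_squared,
               r_squared_unweighted = cu$r_squared_unweighted,
               loq = cu$loq, range_low = cu$range[1], range_high = cu$range[2],
               weighting = cu$weighting, monotone = cu$monotone,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}
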