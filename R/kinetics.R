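#' Elimination kinetics from serial concentrations
#'
#' Noncompartmental phase analysis: log-linear regression of quantified
#' concentrations on time within user-chosen phase windows. Windows are
#' supplied, not auto-detected — phase boundaries in sparse case data are
#' an analyst's call (e.g. excluding an enterohepatic second peak), and
#' automatic breakpoint search is out of scope. Censored points are
#' excluded from fits, never substituted, and make the resulting half-life
#' a lower bound.
#'
#' @name kinetics
NULL

valid_censoring <- c("quantified", "below_loq_detected", "not_detected", "above_range")

#' Concentration-time series for one analyte in one matrix
#'
#' @param points Data frame with columns `day`, `concentration`,
#'   `censoring` (one of `"quantified"`, `"below_loq_detected"`,
#'   `"not_detected"`, `"above_range"`), and optionally `n_aliquots`,
#'   `n_censored`, `aliquot_rsd`. Days must be strictly increasing;
#'   quantified concentrations must be at or above `loq`.
#' @param matrix `"blood"` or `"faeces"`.
#' @param analyte Analyte identifier.
#' @param loq Limit of quantification on the series' concentration scale.
#' @param aliquots Optional raw aliquot data frame retained for audit.
#' @return An object of class `conc_series`.
#' @export
conc_series <- function(points, matrix = c("blood", "faeces"), analyte, loq,
                        aliquots = NULL) {
  matrix <- match.arg(matrix)
  tq_check(is.data.frame(points) &&
             all(c("day", "concentration", "censoring") %in% names(points)),
           "points needs columns day, concentration, censoring",
           class = "tq_invalid_input")
  tq_check(all(points$censoring %in% valid_censoring),
           sprintf("censoring must be one of: %s", paste(valid_censoring, collapse = ", ")),
           class = "tq_invalid_input")
  if (is.unsorted(points$day, strictly = TRUE)) {
    tq_error("days must be strictly increasing", class = "tq_invalid_input")
  }
  tq_check(is.numeric(loq) && loq > 0, "loq must be positive",
           class = "tq_invalid_input")
  quant <- points$censoring == "quantified"
  if (any(quant & (is.na(points$concentration) | points$concentration < loq))) {
    tq_error("quantified points must carry a concentration >= LOQ",
             class = "tq_invalid_input")
  }
  if (!"n_aliquots" %in% names(points)) points$n_aliquots <- 1L
  if (!"aliquot_rsd" %in% names(points)) points$aliquot_rsd <- NA_real_
  structure(list(points = points, matrix = matrix, analyte = analyte,
                 loq = loq, aliquots = aliquots),
            class = "conc_series")
}

#' @export
print.conc_series <- function(x, ...) {
  cat(sprintf("<conc_series> %s in %s, %d sampling days (LOQ %g), %d quantified\n",
              x$analyte, x$matrix, nrow(x$points), x$loq,
              sum(x$points$censoring == "quantified")))
  print(x$points, row.names = FALSE)
  invisible(x)
}

#' Half-life from two concentrations
#'
#' `t_half = (t2 - t1) * ln(2) / ln(c1 / c2)` — the textbook two-point
#' estimate for a log-linear decay.
#'
#' @param t1,t2 Sampling days, `t2 > t1`.
#' @param c1,c2 Concentrations, both positive, `c2 < c1` (a non-decaying
#'   pair raises an error rather than returning a negative half-life).
#' @return Half-life in the time unit of `t1`/`t2`.
#' @examples
#' two_point_half_life(6, 9.8, 11, 1.5)   # 1.85 days, reported as 1.8
#' @export
two_point_half_life <- function(t1, c1, t2, c2) {
  tq_check(t2 > t1, "t2 must exceed t1", class = "tq_usage_error")
  tq_check(c1 > 0 && c2 > 0, "concentrations must be positive",
           class = "tq_invalid_input")
  if (c2 >= c1) {
    tq_error("concentration does not decay between the two points",
             class = "tq_non_decaying")
  }
  (t2 - t1) * log(2) / log(c1 / c2)
}

#' Fit one elimination phase by log-linear regression
#'
#' Ordinary least squares of `ln(concentration)` on day over the quantified
#' points inside `window` (inclusive). The elimination rate is
#' `lambda = -slope` and `t_half = ln(2) / lambda`.
#'
#' The half-life is flagged as a lower bound (`is_lower_bound`) when the
#' data cannot exclude a slower terminal decline: when any in-window or
#' later point is censored below the LOQ, or when the gap before the last
#' in-window point exceeds twice the median spacing of the window's points
#' (the fit then hangs on a single remote observation).
#'
#' @param series A [conc_series()].
#' @param window Numeric `(t_start, t_end)` in days, `t_start < t_end`.
#' @return An object of class `phase_fit`: `window`, `n_points`, `lambda`
#'   (1/day), `half_life` (days, `NA` when the phase does not decay),
#'   `r_squared`, `is_lower_bound`, `censored_excluded`, `non_decaying`.
#' @export
fit_phase <- function(series, window) {
  tq_check(inherits(series, "conc_series"), "series must be a conc_series",
           class = "tq_usage_error")
  tq_check(is.numeric(window) && length(window) == 2L && window[1] < window[2],
           "window must be (t_start, t_end) with t_start < t_end",
           class = "tq_usage_error")
  pts <- series$points
  inside <- pts$day >= window[1] & pts$day <= window[2]
  quant <- inside & pts$censoring == "quantified"
  n <- sum(quant)
  if (n < 2L) {
    tq_error(sprintf("phase window [%g, %g] holds %d quantified point(s); need >= 2",
                     window[1], window[2], n), class = "tq_insufficient_data")
  }
  day <- pts$day[quant]
  lc <- log(pts$concentration[quant])
  fit <- stats::lm(lc ~ day)
  lambda <- -unname(stats::coef(fit)[["day"]])
  non_decaying <- lambda <= 0
  # direct R2 (summary.lm warns on an exactly perfect fit)
  sst <- sum((lc - mean(lc))^2)
  r2 <- if (n == 2L || sst == 0) 1 else 1 - sum(stats::resid(fit)^2) / sst

  censored_after <- pts$day >= window[1] & pts$censoring == "below_loq_detected"
  spacing <- diff(day)
  gap_flag <- length(spacing) >= 2 && spacing[length(spacing)] > 2 * stats::median(spacing)
  structure(
    list(window = window, n_points = n, lambda = lambda,
         half_life = if (non_decaying) NA_real_ else log(2) / lambda,
         r_squared = r2,
         is_lower_bound = any(censored_after) || gap_flag,
         censored_excluded = sum(inside & pts$censoring != "quantified"),
         non_decaying = non_decaying,
         matrix = series$matrix, analyte = series$analyte),
    class = "phase_fit")
}

#' @export
print.phase_fit <- function(x, ...) {
  if (isTRUE(x$insufficient)) {
    cat(sprintf("<phase_fit> %s/%s window [%g, %g]: insufficient quantified data\n",
                x$analyte, x$matrix, x$window[1], x$window[2]))
    return(invisible(x))
  }
  hl <- if (x$non_decaying) "no decay" else
    sprintf("t1/2 = %s%.3g d", if (x$is_lower_bound) "at least " else "", x$half_life)
  cat(sprintf("<phase_fit> %s/%s window [%g, %g]: %s (lambda %.4g /d, n %d, R2 %.3f%s)\n",
              x$analyte, x$matrix, x$window[1], x$window[2], hl, x$lambda,
              x$n_points, x$r_squared,
              if (x$censored_excluded) sprintf(", %d censored excluded", x$censored_excluded) else ""))
  invisible(x)
}

#' Multiphasic summary of a concentration-time series
#'
#' Fits each supplied phase window and reports the quantified points that
#' fall in no window (e.g. an enterohepatic second peak deliberately kept
#' out of both phases) together with the last day with a quantified
#' concentration and the last day with any detectable signal.
#'
#' @param series A [conc_series()].
#' @param windows List of `(t_start, t_end)` windows, non-overlapping and
#'   in increasing order.
#' @return An object of class `biphasic_summary`: `fits` (list of
#'   `phase_fit`), `excluded` (data frame of quantified points outside all
#'   windows), `n_excluded`, `last_quantified_day`, `last_detected_day`.
#' @export
biphasic_summary <- function(series, windows) {
  tq_check(inherits(series, "conc_series"), "series must be a conc_series",
           class = "tq_usage_error")
  tq_check(is.list(windows) && length(windows) >= 1L, "windows must be a list",
           class = "tq_usage_error")
  ends <- vapply(windows, function(w) {
    tq_check(is.numeric(w) && length(w) == 2L && w[1] < w[2],
             "each window must be (t_start, t_end) with t_start < t_end",
             class = "tq_usage_error")
    w
  }, numeric(2))
  if (length(windows) > 1L) {
    for (i in seq_len(ncol(ends) - 1L)) {
      if (ends[2, i] >= ends[1, i + 1L]) {
        tq_error("phase windows must be non-overlapping and increasing",
                 class = "tq_usage_error")
      }
    }
  }
  # a window that cannot be fitted (fewer than 2 quantified points) is
  # reported as such rather than aborting the remaining phases
  fits <- lapply(windows, function(w) {
    tryCatch(fit_phase(series, w), tq_insufficient_data = function(e) {
      structure(list(window = w, n_points = 0L, lambda = NA_real_,
                     half_life = NA_real_, r_squared = NA_real_,
                     is_lower_bound = FALSE, censored_excluded = NA_integer_,
                     non_decaying = FALSE, insufficient = TRUE,
                     matrix = series$matrix, analyte = series$analyte),
                class = "phase_fit")
    })
  })
  pts <- series$points
  in_any <- Reduce(`|`, lapply(windows, function(w) pts$day >= w[1] & pts$day <= w[2]))
  excluded <- pts[pts$censoring == "quantified" & !in_any, , drop = FALSE]
  detected <- pts$censoring %in% c("quantified", "below_loq_detected")
  structure(
    list(fits = fits, excluded = excluded, n_excluded = nrow(excluded),
         last_quantified_day = if (any(pts$censoring == "quantified"))
           max(pts$day[pts$censoring == "quantified"]) else NA_real_,
         last_detected_day = if (any(detected)) max(pts$day[detected]) else NA_real_,
         matrix = series$matrix, analyte = series$analyte),
    class = "biphasic_summary")
}

#' @export
print.biphasic_summary <- function(x, ...) {
  cat(sprintf("<biphasic_summary> %s in %s\n", x$analyte, x$matrix))
  for (f in x$fits) print(f)
  cat(sprintf("  last quantified day %s; last detected day %s; %d quantified point(s) outside all windows\n",
              format(x$last_quantified_day), format(x$last_detected_day), x$n_excluded))
  invisible(x)
}

#' Serialize a multiphasic summary to a plain list (for JSON reports)
#' @param x A `biphasic_summary`.
#' @return A nested list of plain types.
#' @export
pk_report <- function(x) {
  tq_check(inherits(x, "biphasic_summary"), "x must be a biphasic_summary",
           class = "tq_usage_error")
  list(analyte = x$analyte, matrix = x$matrix,
       phases = lapply(x$fits, function(f) {
         list(window = f$window, n_points = f$n_points, lambda_per_day = f$lambda,
              half_life_days = f$half_life, r_squared = f$r_squared,
              is_lower_bound = f$is_lower_bound,
              censored_excluded = f$censored_excluded,
              non_decaying = f$non_decaying,
              insufficient = isTRUE(f$insufficient))
       }),
       n_excluded = x$n_excluded,
       last_quantified_day = x$last_quantified_day,
       last_detected_day = x$last_detected_day)
}
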