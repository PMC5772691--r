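#' Bioanalytical validation battery
#'
#' Per analyte and QC level: within-day and between-day precision (RSD %),
#' bias (%), and the post-extraction spike (Matuszewski) estimators of
#' matrix effect and extraction recovery. Acceptance follows the blanket
#' +/-20% rule at all levels, including the LOQ.
#'
#' @name validate
NULL

#' Within-day precision
#'
#' @param x Measured concentrations of replicates from a single day and
#'   level, at least two.
#' @return RSD in percent: `100 * sd(x) / mean(x)`.
#' @export
within_day_precision <- function(x) {
  tq_check(is.numeric(x) && length(x) >= 2L,
           "within-day precision needs >= 2 replicates", class = "tq_usage_error")
  m <- mean(x)
  if (m == 0) tq_error("RSD undefined: mean concentration is zero",
                       class = "tq_undefined_rsd")
  100 * stats::sd(x) / m
}

#' Between-day (intermediate) precision
#'
#' One-way variance decomposition over days:
#' `s_total^2 = MS_within + max(0, (MS_between - MS_within) / n0)` with
#' `n0` the effective replicates per day, reported as
#' `100 * s_total / grand mean`. With a single replicate per day the
#' within-day mean square has no degrees of freedom and the estimate
#' reduces to the RSD of the daily values. The naive RSD over all
#' observations is attached as attribute `"naive_rsd"` for comparison.
#'
#' @param values Measured concentrations.
#' @param days Parallel vector of day labels; at least two distinct days.
#' @return Intermediate-precision RSD in percent.
#' @export
between_day_precision <- function(values, days) {
  tq_check(is.numeric(values) && length(values) == length(days),
           "values and days must have equal length", class = "tq_usage_error")
  days <- as.factor(days)
  k <- nlevels(days)
  if (k < 2L) tq_error("between-day precision needs >= 2 days",
                       class = "tq_insufficient_design")
  grand <- mean(values)
  if (grand == 0) tq_error("RSD undefined: mean concentration is zero",
                           class = "tq_undefined_rsd")
  ni <- tabulate(days)
  n <- length(values)
  day_means <- tapply(values, days, mean)
  if (n == k) {
    s_tot <- stats::sd(day_means)
  } else {
    ssw <- sum((values - day_means[days])^2)
    msw <- ssw / (n - k)
    msb <- sum(ni * (day_means - grand)^2) / (k - 1)
    n0 <- (n - sum(ni^2) / n) / (k - 1)
    s2_between <- max(0, (msb - msw) / n0)
    s_tot <- sqrt(msw + s2_between)
  }
  out <- 100 * s_tot / grand
  attr(out, "naive_rsd") <- 100 * stats::sd(values) / grand
  out
}

#' Bias of measured concentrations against nominal
#'
#' @param measured Measured concentrations, non-empty.
#' @param nominal Nominal (spiked) concentration, positive.
#' @return Percent bias: `100 * (mean(measured) - nominal) / nominal`
#'   (negative when the method under-recovers).
#' @export
bias <- function(measured, nominal) {
  tq_check(is.numeric(measured) && length(measured) >= 1L,
           "measured concentrations must be a non-empty numeric vector",
           class = "tq_usage_error")
  tq_check(is.numeric(nominal) && nominal > 0, "nominal must be positive",
           class = "tq_usage_error")
  100 * (mean(measured) - nominal) / nominal
}

#' Matrix effect (post-extraction spike design)
#'
#' `ME% = 100 * mean(setB) / mean(setA)` at one concentration level, where
#' set A are neat standards and set B post-extraction matrix spikes across
#' lots. Below 100 is ion suppression, above 100 enhancement.
#'
#' @param neat Set-A responses, >= 2 lots.
#' @param post_spike Set-B responses, same level.
#' @return ME in percent.
#' @export
matrix_effect <- function(neat, post_spike) {
  tq_check(is.numeric(neat) && is.numeric(post_spike) &&
             length(neat) >= 2L && length(post_spike) >= 2L,
           "matrix effect needs >= 2 lots in each set", class = "tq_usage_error")
  if (mean(neat) == 0) tq_error("invalid reference: neat-set mean is zero",
                                class = "tq_invalid_reference")
  100 * mean(post_spike) / mean(neat)
}

#' Extraction recovery (post-extraction spike design)
#'
#' `RE% = 100 * mean(setC) / mean(setB)`: pre-extraction spikes over
#' post-extraction spikes, isolating losses in sample preparation.
#'
#' @param post_spike Set-B responses, >= 2 lots.
#' @param pre_spike Set-C responses, same level.
#' @return RE in percent.
#' @export
extraction_recovery <- function(post_spike, pre_spike) {
  tq_check(is.numeric(post_spike) && is.numeric(pre_spike) &&
             length(post_spike) >= 2L && length(pre_spike) >= 2L,
           "extraction recovery needs >= 2 lots in each set", class = "tq_usage_error")
  if (mean(post_spike) == 0) tq_error("invalid reference: post-spike-set mean is zero",
                                      class = "tq_invalid_reference")
  100 * mean(pre_spike) / mean(post_spike)
}

set_responses <- function(peak_table, analyte, conc = NULL) {
  d <- peak_table[peak_table$analyte == analyte &
                    peak_table$transition_role == "quantifier", , drop = FALSE]
  if (!is.null(conc)) {
    d <- d[abs(d$nominal_conc - conc) < 1e-9 * max(conc, 1), , drop = FALSE]
  }
  response_ratio(d$peak_height, d$is_height)
}

#' Assemble the validation report
#'
#' One row per analyte and QC level with within-/between-day precision,
#' bias, matrix effect, extraction recovery and process efficiency
#' (`ME * RE / 100`). Metrics whose inputs are unavailable (e.g. ME/RE at
#' a QC level absent from the matrix experiment) are reported as `NA` —
#' explicit missing-metric markers, never silently dropped rows. A level is
#' `accepted` when `|bias|` and both precisions are all within the limits
#' (default 20%).
#'
#' @param qc_results Data frame with columns `analyte`, `level`, `day`,
#'   `concentration`, `nominal_conc` of back-calculated QC replicates.
#' @param matrix_sets Optional list with `neat`, `post_spike`, `pre_spike`
#'   `peak_table`s from [generate_matrix_experiment()] (or read from disk).
#' @param limits Named numeric, `c(precision = 20, bias = 20)`.
#' @return Data frame of class `validation_report`.
#' @export
validation_report <- function(qc_results, matrix_sets = NULL,
                              limits = c(precision = 20, bias = 20)) {
  need <- c("analyte", "level", "day", "concentration", "nominal_conc")
  tq_check(is.data.frame(qc_results) && all(need %in% names(qc_results)),
           sprintf("qc_results needs columns: %s", paste(need, collapse = ", ")),
           class = "tq_invalid_input")
  tq_check(all(limits > 0), "acceptance limits must be positive")
  rows <- list()
  for (an in unique(qc_results$analyte)) {
    da <- qc_results[qc_results$analyte == an, , drop = FALSE]
    for (lv in unique(da$level)) {
      d <- da[da$level == lv, , drop = FALSE]
      nominal <- d$nominal_conc[1]
      first_day <- d[d$day == d$day[1], "concentration"]
      wd <- if (length(first_day) >= 2L) within_day_precision(first_day) else NA_real_
      bd <- if (length(unique(d$day)) >= 2L)
        as.numeric(between_day_precision(d$concentration, d$day)) else NA_real_
      bs <- bias(d$concentration, nominal)
      me <- re <- NA_real_
      if (!is.null(matrix_sets)) {
        a_resp <- set_responses(matrix_sets$neat, an, nominal)
        b_resp <- set_responses(matrix_sets$post_spike, an, nominal)
        c_resp <- set_responses(matrix_sets$pre_spike, an, nominal)
        if (length(a_resp) >= 2L && length(b_resp) >= 2L) {
          me <- matrix_effect(a_resp, b_resp)
        }
        if (length(b_resp) >= 2L && length(c_resp) >= 2L) {
          re <- extraction_recovery(b_resp, c_resp)
        }
      }
      core <- c(wd, bd, abs(bs))
      accepted <- !any(is.na(core[1:2])) &&
        all(core <= c(limits[["precision"]], limits[["precision"]], limits[["bias"]]))
      rows[[length(rows) + 1L]] <- data.frame(
        analyte = an, level = lv, nominal_conc = nominal,
        n = nrow(d), n_days = length(unique(d$day)),
        within_day_rsd = wd, between_day_rsd = bd, bias = bs,
        me_percent = me, re_percent = re,
        process_efficiency = me * re / 100,
        accepted = accepted, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("validation_report", "data.frame")
  out
}
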