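#' From peak heights to concentrations
#'
#' Quantification proceeds from the analyte/internal-standard peak-height
#' ratio through the inverted calibration curve, with three layers of QC:
#' the LOQ censoring policy (detected-below-LOQ is a first-class state —
#' "trace amounts" — distinct from not-detected), the qualifier/quantifier
#' ion-ratio identity check, and multi-aliquot aggregation for faecal
#' specimens analysed as 3-6 parallels.
#'
#' @name quantify
NULL

#' Response ratio of a peak record
#'
#' @param peak_height Analyte quantifier peak height, >= 0.
#' @param is_height Internal-standard peak height, strictly positive: a
#'   zero IS height means the injection or extraction failed and the sample
#'   must be rejected, not silently given a ratio.
#' @return `peak_height / is_height`.
#' @export
response_ratio <- function(peak_height, is_height) {
  tq_check(is.numeric(peak_height) && all(peak_height >= 0),
           "peak heights must be >= 0", class = "tq_invalid_input")
  if (!is.numeric(is_height) || any(!is.finite(is_height)) || any(is_height <= 0)) {
    tq_error("internal-standard height is zero or invalid: sample rejected",
             class = "tq_internal_standard_failure")
  }
  peak_height / is_height
}

#' Ion-ratio identity check
#'
#' The qualifier/quantifier height ratio must fall within a relative
#' tolerance (default +/-30%, a stated convention) of the expected ratio,
#' which is normally taken from the mean of the calibrators in the same
#' batch (see [expected_ion_ratios()]).
#'
#' @param quant_height Quantifier peak height, positive.
#' @param qual_height Qualifier peak height, >= 0.
#' @param expected_ratio Expected qualifier/quantifier ratio, positive.
#' @param tolerance Relative tolerance, default 0.30.
#' @return `TRUE` if the observed ratio passes.
#' @export
ion_ratio_check <- function(quant_height, qual_height, expected_ratio,
                            tolerance = 0.30) {
  if (!is.numeric(expected_ratio) || !is.finite(expected_ratio) || expected_ratio <= 0) {
    tq_error("expected ion ratio must be positive", class = "tq_configuration_error")
  }
  tq_check(is.numeric(quant_height) && all(quant_height > 0),
           "quantifier height must be positive for an ion-ratio check",
           class = "tq_invalid_input")
  tq_check(tolerance > 0, "tolerance must be positive")
  # tiny relative slack so a ratio sitting exactly on the boundary passes
  abs(qual_height / quant_height - expected_ratio) <=
    tolerance * expected_ratio * (1 + 1e-12) + 1e-15
}

#' Batch expected ion ratios from calibrators
#'
#' @param peak_table A `peak_table` containing calibrator records with both
#'   quantifier and qualifier transitions.
#' @return Named numeric vector of mean qualifier/quantifier ratios per
#'   analyte.
#' @export
expected_ion_ratios <- function(peak_table) {
  cal <- peak_table[peak_table$role == "calibrator", , drop = FALSE]
  tq_check(nrow(cal) > 0, "peak table holds no calibrator records",
           class = "tq_invalid_input")
  out <- vapply(split(cal, cal$analyte), function(d) {
    byid <- split(d, d$sample_id)
    ratios <- vapply(byid, function(s) {
      qh <- s$peak_height[s$transition_role == "quantifier"]
      lh <- s$peak_height[s$transition_role == "qualifier"]
      if (length(qh) != 1L || length(lh) < 1L || qh <= 0) return(NA_real_)
      mean(lh) / qh
    }, numeric(1))
    mean(ratios, na.rm = TRUE)
  }, numeric(1))
  out
}

#' Quantify one sample from its peak records
#'
#' Applies the censoring policy: `quantified` when the back-calculated
#' concentration is at or above the LOQ; `below_loq_detected` when signal
#' is present but the concentration falls below the LOQ (the concentration
#' estimate is retained for inspection); `not_detected` when the quantifier
#' height is zero; `above_range` when the response exceeds the curve's
#' quantifiable ceiling (no extrapolation).
#'
#' @param curve A `calibration_curve` for the sample's analyte.
#' @param records Data frame of peak-table rows for one sample and analyte
#'   (exactly one quantifier row; qualifier rows optional).
#' @param expected_ratio Expected ion ratio for the identity check
#'   (`NA` skips the check).
#' @param ion_ratio_tolerance Relative tolerance, default 0.30.
#' @param loq LOQ override; defaults to the curve's.
#' @return One-row data frame of class `sample_result`: `sample_id`,
#'   `analyte`, `matrix`, `day`, `aliquot_index`, `concentration`,
#'   `censoring`, `ion_ratio_ok`, `n_aliquots`, `n_censored`, `aliquot_rsd`.
#' @export
quantify_sample <- function(curve, records, expected_ratio = NA_real_,
                            ion_ratio_tolerance = 0.30, loq = NULL) {
  tq_check(inherits(curve, "calibration_curve"), "curve must be a calibration_curve",
           class = "tq_usage_error")
  loq <- loq %||% curve$loq
  qrows <- records[records$transition_role == "quantifier", , drop = FALSE]
  if (nrow(qrows) != 1L) {
    tq_error(sprintf("sample '%s': expected exactly one quantifier record, found %d",
                     records$sample_id[1] %||% "?", nrow(qrows)),
             class = "tq_malformed_sample")
  }
  qual <- records[records$transition_role == "qualifier", , drop = FALSE]
  qh <- qrows$peak_height

  conc <- NA_real_
  if (qh == 0) {
    censoring <- "not_detected"
  } else {
    ratio <- response_ratio(qh, qrows$is_height)
    res <- tryCatch(
      list(conc = back_calculate(curve, ratio), err = NULL),
      tq_out_of_range = function(e) list(conc = NA_real_, err = e$direction))
    if (is.null(res$err)) {
      conc <- res$conc
      # relative epsilon so a calibrator sitting exactly at the LOQ does not
      # censor on floating-point round-off
      censoring <- if (conc >= loq * (1 - 1e-9)) "quantified" else "below_loq_detected"
    } else {
      censoring <- if (res$err == "above") "above_range" else "below_loq_detected"
    }
  }

  ion_ok <- NA
  if (nrow(qual) >= 1L && is.finite(expected_ratio) && qh > 0) {
    ion_ok <- ion_ratio_check(qh, mean(qual$peak_height), expected_ratio,
                              ion_ratio_tolerance)
  }
  out <- data.frame(sample_id = qrows$sample_id, analyte = qrows$analyte,
                    matrix = qrows$matrix %||% NA_character_,
                    day = qrows$day %||% NA_real_,
                    aliquot_index = qrows$aliquot_index %||% NA_integer_,
                    concentration = conc, censoring = censoring,
                    ion_ratio_ok = ion_ok, n_aliquots = 1L, n_censored = 0L,
                    aliquot_rsd = NA_real_, stringsAsFactors = FALSE)
  class(out) <- c("sample_result", "data.frame")
  out
}

#' Quantify every sample in a peak table
#'
#' Groups a peak table by sample and analyte, back-calculates each against
#' the analyte's curve, and attaches ion-ratio QC using batch expected
#' ratios derived from the table's own calibrators when present.
#'
#' @param curves Named list of `calibration_curve`s keyed by analyte.
#' @param peak_table A `peak_table`.
#' @param roles Which sample roles to quantify (default: everything except
#'   the matrix-experiment sets).
#' @param ... Passed to [quantify_sample()].
#' @return Data frame of `sample_result` rows.
#' @export
quantify_table <- function(curves, peak_table,
                           roles = c("calibrator", "qc", "unknown"), ...) {
  tab <- peak_table[peak_table$role %in% roles, , drop = FALSE]
  tq_check(nrow(tab) > 0, "no records with the requested roles",
           class = "tq_invalid_input")
  ratios <- tryCatch(expected_ion_ratios(peak_table),
                     toxiquant_error = function(e) NULL)
  keys <- interaction(tab$sample_id, tab$analyte, drop = TRUE)
  res <- lapply(split(tab, keys), function(d) {
    an <- d$analyte[1]
    curve <- curves[[an]]
    if (is.null(curve)) {
      tq_error(sprintf("no calibration curve for analyte '%s'", an),
               class = "tq_usage_error")
    }
    quantify_sample(curve, d,
                    expected_ratio = if (is.null(ratios)) NA_real_ else
                      ratios[[an]] %||% NA_real_, ...)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Aggregate parallel aliquots of one specimen
#'
#' Faecal samples are analysed as 3-6 parallel aliquots. The reported
#' concentration is the arithmetic mean of the quantified aliquots with
#' the sample (n-1) relative standard deviation; censored aliquots are
#' counted and excluded from the mean (optionally substituted by LOQ/2).
#' When all aliquots are censored the aggregate inherits the most
#' informative censoring state (`above_range`, else `below_loq_detected`,
#' else `not_detected`).
#'
#' @param results Data frame of `sample_result` rows for one specimen and
#'   analyte.
#' @param substitute_half_loq If `TRUE`, below-LOQ-detected aliquots enter
#'   the mean as `loq / 2`. Off by default.
#' @param loq Required when `substitute_half_loq = TRUE`.
#' @return One-row `sample_result` with `n_aliquots`, `n_censored` and
#'   `aliquot_rsd` filled in.
#' @export
aggregate_aliquots <- function(results, substitute_half_loq = FALSE, loq = NULL) {
  tq_check(is.data.frame(results) && nrow(results) >= 1L,
           "results must be a non-empty data frame", class = "tq_usage_error")
  tq_check(length(unique(results$analyte)) == 1L,
           "aliquots must belong to a single analyte", class = "tq_usage_error")
  vals <- results$concentration[results$censoring == "quantified"]
  if (substitute_half_loq) {
    tq_check(!is.null(loq), "substitution requires an explicit loq")
    vals <- c(vals, rep(loq / 2, sum(results$censoring == "below_loq_detected")))
  }
  out <- results[1L, , drop = FALSE]
  out$aliquot_index <- NA_integer_
  out$n_aliquots <- nrow(results)
  out$n_censored <- sum(results$censoring != "quantified")
  if (length(vals) >= 1L) {
    out$concentration <- mean(vals)
    out$censoring <- "quantified"
    out$aliquot_rsd <- if (length(vals) >= 2L) 100 * stats::sd(vals) / mean(vals)
                       else NA_real_
  } else {
    states <- results$censoring
    out$concentration <- NA_real_
    out$censoring <- if ("above_range" %in% states) "above_range"
                     else if ("below_loq_detected" %in% states) "below_loq_detected"
                     else "not_detected"
    out$aliquot_rsd <- NA_real_
  }
  out$ion_ratio_ok <- if (all(is.na(results$ion_ratio_ok))) NA
                      else all(results$ion_ratio_ok, na.rm = TRUE)
  rownames(out) <- NULL
  out
}
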