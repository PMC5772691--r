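# Independent oracles and shared fixtures for the test suite.

# Closed-form weighted least squares for y ~ 1 + x + x^2 via the normal
# equations -- deliberately a different computational path from lm()'s QR.
wls_quad_oracle <- function(x, y, w) {
  X <- cbind(1, x, x^2)
  beta <- solve(t(X) %*% (w * X), t(X) %*% (w * y))
  c(a = beta[3], b = beta[2], c = beta[1])
}

# Bisection inverse of a calibration curve on its increasing branch.
bisect_oracle <- function(curve, response, lo = 0, hi = 1.2 * curve$range[2],
                          tol = 1e-12) {
  f <- function(x) predict(curve, x) - response
  stopifnot(f(lo) <= 0, f(hi) >= 0)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
    if (hi - lo < tol * max(1, hi)) break
  }
  (lo + hi) / 2
}

# Hand-buildable calibration curve without fitting (for policy tests).
make_curve <- function(a, b, c, range, loq = range[1], analyte = "test") {
  structure(list(analyte = analyte, coefficients = c(a = a, b = b, c = c),
                 weighting = "1/x", range = range, r_squared = 1,
                 r_squared_unweighted = 1, loq = loq, monotone = TRUE,
                 n_levels = 7L, n_points = 7L),
            class = "calibration_curve")
}

# One-row peak-table fragment for quantify_sample tests.
peak_record <- function(sample_id = "s1", analyte = "test", quant = 100,
                        qual = NA, is_height = 1000, matrix = "blood",
                        role = "unknown", nominal = NA, day = NA) {
  roles <- c("quantifier", if (!is.na(qual)) "qualifier")
  data.frame(sample_id = sample_id, analyte = analyte, matrix = matrix,
             role = role, transition_role = roles,
             peak_height = c(quant, if (!is.na(qual)) qual),
             is_height = is_height, nominal_conc = nominal, day = day,
             aliquot_index = NA_integer_, stringsAsFactors = FALSE)
}

# The printed calibration endpoints of the bundled six-compound panel.
printed_ranges <- list(
  coumatetralyl = c(1.5, 731), bromadiolone = c(2.6, 1319),
  difenacoum = c(2.2, 1111), flocoumafen = c(2.7, 1356),
  brodifacoum = c(2.6, 1309), difethialone = c(2.7, 1349))

test_panel <- function() default_panel()

single_analyte_panel <- function(name) {
  p <- default_panel()
  analyte_panel(list(p$analytes[[name]]), p$internal_standard, name = name)
}

# quantifier response ratios of one analyte (optionally one level) from a
# peak table -- test-side counterpart of the package-internal extraction
set_responses_test <- function(pt, analyte, conc = NULL) {
  d <- pt[pt$analyte == analyte & pt$transition_role == "quantifier", ]
  if (!is.null(conc)) d <- d[abs(d$nominal_conc - conc) < 1e-9 * conc, ]
  d$peak_height / d$is_height
}
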