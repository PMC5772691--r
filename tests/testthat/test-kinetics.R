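series_from <- function(day, conc, loq = 1.5, matrix = "faeces",
                        censoring = NULL) {
  censoring <- censoring %||% ifelse(conc >= loq, "quantified", "below_loq_detected")
  toxiquant::conc_series(
    data.frame(day = day, concentration = conc, censoring = censoring),
    matrix = matrix, analyte = "coumatetralyl", loq = loq)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("two-point half-life matches the closed form", {
  expect_equal(two_point_half_life(6, 9.8, 11, 1.5),
               5 * log(2) / log(9.8 / 1.5), tolerance = 1e-12)
  expect_equal(two_point_half_life(0, 10, 5, 5), 5)       # exact halving
  expect_error(two_point_half_life(6, 5, 11, 5), class = "tq_non_decaying")
  expect_error(two_point_half_life(6, 5, 11, 9), class = "tq_non_decaying")
  expect_error(two_point_half_life(11, 9.8, 6, 1.5), class = "tq_usage_error")
})

test_that("phase fits are exact on noiseless exponentials", {
  day <- c(6, 7, 11, 18, 22)
  h <- 3.7
  s <- series_from(day, 800 * 2^(-day / h))   # stays above the LOQ throughout
  f <- fit_phase(s, c(6, 22))
  expect_equal(f$half_life, h, tolerance = 1e-10)
  expect_equal(f$r_squared, 1, tolerance = 1e-9)
  expect_false(f$is_lower_bound)
  # a two-point window reduces to the two-point estimator
  f2 <- fit_phase(s, c(6, 7))
  expect_equal(f2$half_life,
               two_point_half_life(6, s$points$concentration[1],
                                   7, s$points$concentration[2]),
               tolerance = 1e-12)
})

test_that("half-lives are invariant to time shifts and concentration scale", {
  withr::with_seed(30, {
    for (i in 1:20) {
      day <- sort(sample(5:200, 6))
      conc <- 500 * 2^(-day / 40) * exp(rnorm(6, 0, 0.1))
      s0 <- series_from(day, conc, loq = 1e-6)
      f0 <- fit_phase(s0, range(day))
      fshift <- fit_phase(series_from(day + 17, conc, loq = 1e-6),
                          range(day) + 17)
      fscale <- fit_phase(series_from(day, 3.21 * conc, loq = 1e-6), range(day))
      expect_equal(fshift$half_life, f0$half_life, tolerance = 1e-9)
      expect_equal(fscale$half_life, f0$half_life, tolerance = 1e-9)
    }
  })
})

test_that("censoring drives the lower-bound flag, never silently drops points", {
  day <- c(6, 11, 18, 50)
  s <- series_from(day, c(9.8, 1.8, 0.9, 0.4))   # last two below LOQ 1.5
  f <- fit_phase(s, c(6, 11))
  expect_equal(f$n_points, 2L)
  expect_true(f$is_lower_bound)          # trailing censored points
  expect_equal(f$censored_excluded, 0L)
  # same window, series truncated before the censored tail: flag may clear
  s2 <- series_from(day[1:2], c(9.8, 1.8))
  f2 <- fit_phase(s2, c(6, 11))
  expect_false(f2$is_lower_bound)
  expect_gte(f$is_lower_bound, f2$is_lower_bound)  # censoring monotonicity
  # in-window censored point: excluded from the fit and counted
  s3 <- series_from(c(6, 8, 11), c(9.8, 1.2, 1.6))
  f3 <- fit_phase(s3, c(6, 11))
  expect_equal(f3$n_points, 2L)
  expect_equal(f3$censored_excluded, 1L)
  expect_true(f3$is_lower_bound)
})

test_that("a remote last point makes the half-life a lower bound", {
  # spacings 29, 28, 83, 218: the 218-day gap before the tail point
  # exceeds twice the median spacing
  day <- c(64, 93, 121, 204, 422)
  s <- series_from(day, 60 * 2^(-day / 81))
  f <- fit_phase(s, c(64, 422))
  expect_true(f$is_lower_bound)
  expect_equal(f$half_life, 81, tolerance = 1e-9)
})

test_that("non-decaying phases are flagged, not given negative half-lives", {
  s <- series_from(c(6, 11, 18), c(2, 3, 4))
  f <- fit_phase(s, c(6, 18))
  expect_true(f$non_decaying)
  expect_true(is.na(f$half_life))
  expect_error(fit_phase(s, c(100, 200)), class = "tq_insufficient_data")
})

test_that("biphasic summaries report exclusions and last days", {
  cp <- generate_case_profile(pk_profile(), n_aliquots = 6, seed = 12)
  # windows excluding the enterohepatic bump days 24-39
  bs <- biphasic_summary(cp$faeces, list(c(6, 22), c(50, 513)))
  expect_equal(bs$excluded$day[bs$excluded$day >= 24 & bs$excluded$day <= 39],
               c(24, 32, 39))
  expect_error(biphasic_summary(cp$faeces, list(c(6, 50), c(40, 100))),
               class = "tq_usage_error")
  # blood: quantified early, then varies below LOQ -- last days differ
  bb <- biphasic_summary(cp$blood, list(c(6, 11)))
  expect_lt(bb$last_quantified_day, bb$last_detected_day)
  expect_true(bb$fits[[1]]$is_lower_bound)   # trailing censored tail
})

test_that("case-schedule simulations recover both half-lives", {
  # 500 seeded case profiles, six parallels, aliquot RSD 25%; each phase
  # window must recover its half-life within 15% in at least 90% of runs
  hits <- vapply(1:500, function(s) {
    cp <- generate_case_profile(pk_profile(), n_aliquots = 6, seed = s)
    fa <- fit_phase(cp$faeces, c(6, 11))
    fb <- fit_phase(cp$faeces, c(64, 422))
    c(abs(fa$half_life - 1.8) / 1.8 <= 0.15,
      abs(fb$half_life - 81) / 81 <= 0.15)
  }, logical(2))
  expect_gte(mean(hits[1, ] & hits[2, ]), 0.90)
})
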