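test_that("within-day precision is the sample RSD", {
  expect_equal(within_day_precision(c(5, 5, 5, 5)), 0)
  expect_equal(within_day_precision(c(90, 100, 110)), 10)
  expect_error(within_day_precision(100), class = "tq_usage_error")
  expect_error(within_day_precision(c(-1, 1)), class = "tq_undefined_rsd")
})

test_that("between-day precision matches a hand-worked variance decomposition", {
  # 2 days x 2 replicates: MSW = 8, MSB = 64, n0 = 2
  # s_total^2 = 8 + (64 - 8)/2 = 36; RSD = 100 * 6 / 104
  vals <- c(98, 102, 106, 110)
  days <- c(1, 1, 2, 2)
  expect_equal(as.numeric(between_day_precision(vals, days)), 600 / 104,
               tolerance = 1e-12)
  expect_equal(attr(between_day_precision(vals, days), "naive_rsd"),
               100 * sd(vals) / mean(vals))
  # identical day means, zero within-day spread
  expect_equal(as.numeric(between_day_precision(c(5, 5, 5, 5), c(1, 1, 2, 2))), 0)
  # single replicate per day: RSD of the daily values
  expect_equal(as.numeric(between_day_precision(c(90, 100, 110), 1:3)),
               100 * sd(c(90, 100, 110)) / 100)
  expect_error(between_day_precision(c(1, 2), c(1, 1)),
               class = "tq_insufficient_design")
})

test_that("precision estimators recover generating variance components", {
  # within-day: n = 6 replicates at CV 5% over 1000 seeds
  within <- withr::with_seed(14, {
    sdl <- sqrt(log(1 + 0.05^2))
    replicate(1000, within_day_precision(100 * exp(rnorm(6, -sdl^2 / 2, sdl))))
  })
  expect_equal(mean(within), 5, tolerance = 0.1)

  # between-day CV 8% on top of within-day 4%: recovered total near
  # sqrt(0.08^2 + 0.04^2) = 8.94%, within 15% over 500 seeds
  totals <- withr::with_seed(15, {
    replicate(500, {
      day_f <- rep(exp(rnorm(6, 0, 0.08)), each = 6)
      vals <- 100 * day_f * exp(rnorm(36, 0, 0.04))
      as.numeric(between_day_precision(vals, rep(1:6, each = 6)))
    })
  })
  expect_equal(mean(totals), 100 * sqrt(0.08^2 + 0.04^2), tolerance = 0.15)
})

test_that("bias follows the Table-style sign convention", {
  expect_equal(bias(c(100, 100), 100), 0)
  expect_equal(bias(96.5, 100), -3.5)
  expect_error(bias(numeric(0), 100), class = "tq_usage_error")
  expect_error(bias(100, 0), class = "tq_usage_error")
  # a 10% recovery shortfall not corrected by the calibration forces -10%
  measured <- withr::with_seed(16, 100 * 0.9 * exp(rnorm(6, 0, 0.03)))
  expect_equal(bias(measured, 100), -10, tolerance = 0.25)
})

test_that("matrix effect and recovery are the Matuszewski set ratios", {
  A <- c(1.0, 1.1, 0.9, 1.05, 0.95)
  expect_equal(matrix_effect(A, A), 100)
  expect_equal(matrix_effect(A, 0.6 * A), 60)
  expect_equal(extraction_recovery(A, A), 100)
  expect_equal(extraction_recovery(A, 0.25 * A), 25)
  expect_error(matrix_effect(c(0, 0), c(1, 1)), class = "tq_invalid_reference")
  expect_error(matrix_effect(1, 1), class = "tq_usage_error")
})

test_that("ME and RE are recovered from the generator at the 5-lot design", {
  panel <- single_analyte_panel("brodifacoum")
  models <- list(brodifacoum = response_model(a1 = 1e-3, noise_cv = 0.05,
                                              matrix_effect = 0.85, recovery = 0.6))
  est <- vapply(1:200, function(s) {
    mx <- generate_matrix_experiment(panel, models = models, n_lots = 5,
                                     lot_cv = 0.1, seed = 1000 + s)
    lv <- unique(mx$neat$nominal_conc)[1]
    c(matrix_effect(set_responses_test(mx$neat, "brodifacoum", lv),
                    set_responses_test(mx$post_spike, "brodifacoum", lv)),
      extraction_recovery(set_responses_test(mx$post_spike, "brodifacoum", lv),
                          set_responses_test(mx$pre_spike, "brodifacoum", lv)))
  }, numeric(2))
  expect_lt(abs(mean(est[1, ]) - 85), 5)
  expect_lt(abs(mean(est[2, ]) - 60), 5)
})

test_that("estimators are scale invariant", {
  A <- c(1.0, 1.1, 0.9); B <- c(0.85, 0.9, 0.8); k <- 137.5
  expect_equal(matrix_effect(k * A, k * B), matrix_effect(A, B))
  expect_equal(extraction_recovery(k * A, k * B), extraction_recovery(A, B))
  expect_equal(within_day_precision(k * A), within_day_precision(A))
  expect_equal(as.numeric(between_day_precision(k * c(A, B), rep(1:2, each = 3))),
               as.numeric(between_day_precision(c(A, B), rep(1:2, each = 3))))
})

test_that("the validation report applies the +/-20% acceptance rule", {
  qc <- expand.grid(day = 1:2, rep = 1:3)
  mk <- function(an, lv, conc, nominal) {
    data.frame(analyte = an, level = lv, day = qc$day,
               concentration = conc, nominal_conc = nominal)
  }
  good <- mk("coumatetralyl", "low", c(4.4, 4.6, 4.5, 4.7, 4.5, 4.4), 4.5)
  bad <- mk("brodifacoum", "low", rep(100 * (1 - 0.21), 6), 100)   # bias -21%
  rep1 <- validation_report(rbind(good, bad))
  expect_true(rep1$accepted[rep1$analyte == "coumatetralyl"])
  expect_false(rep1$accepted[rep1$analyte == "brodifacoum"])
  expect_equal(rep1$bias[rep1$analyte == "brodifacoum"], -21)
  # missing-metric markers when no matrix experiment is supplied
  expect_true(all(is.na(rep1$me_percent)))
})

test_that("process efficiency is the ME x RE product", {
  panel <- single_analyte_panel("difethialone")
  models <- list(difethialone = response_model(a1 = 1e-3, noise_cv = 0,
                                               matrix_effect = 0.60, recovery = 0.50))
  mx <- generate_matrix_experiment(panel, models = models, lot_cv = 0, seed = 6)
  nominal <- unique(mx$neat$nominal_conc)[1]
  qc <- data.frame(analyte = "difethialone", level = "low", day = rep(1:2, 3),
                   concentration = nominal, nominal_conc = nominal)
  rep2 <- validation_report(qc, mx)
  expect_equal(rep2$me_percent, 60, tolerance = 1e-9)
  expect_equal(rep2$re_percent, 50, tolerance = 1e-9)
  expect_equal(rep2$process_efficiency, 30, tolerance = 1e-9)
  expect_equal(rep2$process_efficiency,
               rep2$me_percent * rep2$re_percent / 100, tolerance = 1e-9)
})
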