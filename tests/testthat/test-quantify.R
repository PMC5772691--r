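test_that("response ratios reject internal-standard failures", {
  expect_equal(response_ratio(500, 1000), 0.5)
  expect_equal(response_ratio(0, 1000), 0)
  expect_error(response_ratio(500, 0), class = "tq_internal_standard_failure")
  expect_error(response_ratio(-1, 1000), class = "tq_invalid_input")
})

test_that("ion-ratio check applies a relative tolerance", {
  expect_true(ion_ratio_check(100, 45, expected_ratio = 0.45))
  expect_false(ion_ratio_check(100, 50, expected_ratio = 1.0))   # 0.5 vs 1.0
  expect_true(ion_ratio_check(100, 70, expected_ratio = 1.0))    # on the edge
  expect_error(ion_ratio_check(100, 45, expected_ratio = 0), class = "tq_configuration_error")
})

test_that("synthetic batches pass ion-ratio QC at a >= 99% rate", {
  panel <- single_analyte_panel("coumatetralyl")
  models <- list(coumatetralyl = response_model(a1 = 2e-3, noise_cv = 0.05))
  cal <- generate_calibration_set(panel, replicates = 150, models = models, seed = 9)
  expected <- expected_ion_ratios(cal)
  q <- cal[cal$transition_role == "quantifier", ]
  l <- cal[cal$transition_role == "qualifier", ]
  l <- l[match(q$sample_id, l$sample_id), ]
  ok <- ion_ratio_check(q$peak_height, l$peak_height, expected[["coumatetralyl"]])
  expect_gte(mean(ok), 0.99)
  expect_gt(length(ok), 1000)
})

test_that("quantify_sample assigns the censoring states", {
  cu <- make_curve(a = 0, b = 0.01, c = 0, range = c(1.5, 731), loq = 1.5)
  # response mapping to 2.1 ng/g with LOQ 1.5 -> quantified
  r <- quantify_sample(cu, peak_record(quant = 0.021 * 1000, is_height = 1000))
  expect_equal(r$censoring, "quantified")
  expect_equal(r$concentration, 2.1, tolerance = 1e-12)
  # response mapping to 0.8 * LOQ -> detected but below LOQ, value retained
  r <- quantify_sample(cu, peak_record(quant = 0.01 * 0.8 * 1.5 * 1000))
  expect_equal(r$censoring, "below_loq_detected")
  expect_equal(r$concentration, 1.2, tolerance = 1e-12)
  # zero quantifier height -> not detected
  r <- quantify_sample(cu, peak_record(quant = 0))
  expect_equal(r$censoring, "not_detected")
  # response beyond the 1.2x ceiling -> above range, no extrapolation
  r <- quantify_sample(cu, peak_record(quant = 0.01 * 2000 * 1000))
  expect_equal(r$censoring, "above_range")
  expect_true(is.na(r$concentration))
  # a record without a quantifier row is malformed
  bad <- peak_record(); bad$transition_role <- "qualifier"
  expect_error(quantify_sample(cu, bad), class = "tq_malformed_sample")
})

test_that("censoring is monotone in the quantifier response", {
  cu <- make_curve(a = -3e-7, b = 2e-3, c = 1e-3, range = c(1.5, 731))
  rank_of <- c(not_detected = 0, below_loq_detected = 1, quantified = 2,
               above_range = 3)
  heights <- seq(0, 2.2e3, length.out = 60)
  states <- vapply(heights, function(h)
    quantify_sample(cu, peak_record(quant = h, is_height = 1000))$censoring,
    character(1))
  expect_true(all(diff(rank_of[states]) >= 0))
})

test_that("aliquot aggregation reports mean, RSD and censored counts", {
  cu <- make_curve(a = 0, b = 0.01, c = 0, range = c(1.5, 731))
  mk <- function(conc) quantify_sample(cu, peak_record(quant = conc * 0.01 * 1000))
  agg <- aggregate_aliquots(rbind(mk(2.0), mk(2.1), mk(2.2)))
  expect_equal(agg$concentration, 2.1, tolerance = 1e-12)
  expect_equal(agg$aliquot_rsd, 100 * sd(c(2.0, 2.1, 2.2)) / 2.1, tolerance = 1e-9)
  expect_equal(agg$n_aliquots, 3L)

  same <- aggregate_aliquots(rbind(mk(5), mk(5), mk(5)))
  expect_equal(same$aliquot_rsd, 0)

  # one censored aliquot is excluded from the mean but counted
  mixed <- aggregate_aliquots(rbind(mk(2.0), mk(2.2), mk(0.8)))
  expect_equal(mixed$concentration, 2.1, tolerance = 1e-12)
  expect_equal(mixed$n_censored, 1L)

  # all censored: inherits the most informative state
  allc <- aggregate_aliquots(rbind(mk(0.8), mk(0.9)))
  expect_equal(allc$censoring, "below_loq_detected")
  expect_true(is.na(allc$concentration))

  # optional LOQ/2 substitution
  sub <- aggregate_aliquots(rbind(mk(2.0), mk(0.8)), substitute_half_loq = TRUE,
                            loq = 1.5)
  expect_equal(sub$concentration, mean(c(2.0, 0.75)), tolerance = 1e-12)
})

test_that("simulated faecal parallels land in the reported RSD band", {
  # 500 specimens of 6 parallels at 25% aliquot CV: the observed per-specimen
  # RSDs should centre near 25% and their median must fall within the 4-41%
  # band reported for the case samples
  p <- pk_profile(aliquot_rsd = 0.25)
  withr::with_seed(77, {
    truth <- 50
    rsds <- replicate(500, {
      v <- truth * exp(rnorm(6, -0.5 * log(1.0625), sqrt(log(1.0625))))
      100 * sd(v) / mean(v)
    })
  })
  expect_gt(median(rsds), 4)
  expect_lt(median(rsds), 41)
  expect_equal(median(rsds), 25, tolerance = 0.15)
  # and the package generator reports the same statistic per sampling day
  cp <- generate_case_profile(p, n_aliquots = 6, seed = 21)
  day_rsd <- cp$faeces$points$aliquot_rsd
  expect_true(all(is.finite(day_rsd[cp$faeces$points$censoring == "quantified" &
                                      cp$faeces$points$n_censored == 0])))
  expect_gt(median(day_rsd, na.rm = TRUE), 4)
  expect_lt(median(day_rsd, na.rm = TRUE), 41)
})
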