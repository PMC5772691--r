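#' Synthetic instrument and case-profile generator
#'
#' These functions replace the mass spectrometer and the animal: they
#' generate calibration and QC peak tables, the three-set post-extraction
#' spike (Matuszewski) matrix experiment, and case-like biphasic
#' concentration-time profiles with multi-aliquot faecal sampling. All
#' randomness is driven by explicit `seed` arguments (the caller's global
#' RNG state is left untouched); noise is multiplicative lognormal with a
#' stated coefficient of variation — exactly the constant-relative-error
#' regime that motivates 1/x calibration weighting.
#'
#' @name synthgen
NULL

#' Instrument response model for one analyte
#'
#' The mean response ratio at concentration `x` is
#' `s * (a2*x^2 + a1*x + a0)` where the set-dependent scale `s` is 1 for
#' neat standards, the matrix-effect factor `m` for post-extraction spikes,
#' and `m * r` (with extraction recovery `r`) for pre-extraction spikes and
#' routine samples. Observed responses carry multiplicative lognormal noise
#' with CV `noise_cv`.
#'
#' @param a1 Linear response per unit concentration, positive.
#' @param a2 Curvature (response per concentration squared); slightly
#'   negative values emulate detector saturation at the top of a wide range.
#' @param a0 Intercept (background), >= 0.
#' @param noise_cv Relative standard deviation of the multiplicative noise.
#' @param matrix_effect Factor `m`, in (0, 1.5]; < 1 is ion suppression.
#' @param recovery Extraction recovery `r`, in (0, 1].
#' @param range Optional calibration range on which the mean response must
#'   be strictly increasing (`2*a2*x + a1 > 0` checked at the endpoints).
#' @return An object of class `response_model`.
#' @export
response_model <- function(a1, a2 = 0, a0 = 0, noise_cv = 0,
                           matrix_effect = 1, recovery = 1, range = NULL) {
  tq_check(is.numeric(a1) && a1 > 0, "a1 (slope) must be positive",
           class = "tq_invalid_input")
  tq_check(is.numeric(noise_cv) && noise_cv >= 0, "noise_cv must be >= 0",
           class = "tq_invalid_input")
  tq_check(matrix_effect > 0 && matrix_effect <= 1.5,
           "matrix_effect must lie in (0, 1.5]", class = "tq_invalid_input")
  tq_check(recovery > 0 && recovery <= 1, "recovery must lie in (0, 1]",
           class = "tq_invalid_input")
  if (!is.null(range)) {
    tq_check(all(2 * a2 * range + a1 > 0),
             "response model is not strictly increasing over the calibration range",
             class = "tq_invalid_input")
  }
  structure(list(a2 = a2, a1 = a1, a0 = a0, noise_cv = noise_cv,
                 matrix_effect = matrix_effect, recovery = recovery,
                 range = range),
            class = "response_model")
}

#' Default per-analyte response models
#'
#' Slopes are scaled so the response ratio at the top calibrator is near
#' 1.3; curvature is mildly saturating (the derivative at the top of the
#' range is 60% of the initial slope). Matrix-effect and recovery defaults
#' follow the validated behaviour of the assay: little suppression and good
#' recovery from blood; ion suppression and markedly lower recovery
#' (brodifacoum 25%) from faeces, coumatetralyl excepted from suppression.
#'
#' @param panel An `analyte_panel`.
#' @param matrix `"blood"` or `"faeces"`.
#' @param noise_cv Instrument noise CV shared by all analytes.
#' @return Named list of `response_model` objects, one per analyte.
#' @export
default_response_models <- function(panel, matrix = c("blood", "faeces"),
                                    noise_cv = 0.05) {
  matrix <- match.arg(matrix)
  me <- list(
    blood  = c(coumatetralyl = 0.90, bromadiolone = 1.00, difenacoum = 1.01,
               flocoumafen = 0.95, brodifacoum = 0.93, difethialone = 0.86),
    faeces = c(coumatetralyl = 1.09, bromadiolone = 0.63, difenacoum = 0.62,
               flocoumafen = 0.45, brodifacoum = 0.32, difethialone = 0.31))
  re <- list(
    blood  = c(coumatetralyl = 0.93, bromadiolone = 0.97, difenacoum = 0.74,
               flocoumafen = 0.92, brodifacoum = 0.61, difethialone = 0.69),
    faeces = c(coumatetralyl = 0.66, bromadiolone = 0.32, difenacoum = 0.26,
               flocoumafen = 0.18, brodifacoum = 0.25, difethialone = 0.22))
  out <- lapply(panel$analytes, function(a) {
    high <- a$calibration_range[2]
    a1 <- 1.6 / high
    response_model(a1 = a1, a2 = -0.2 * a1 / high, a0 = 0, noise_cv = noise_cv,
                   matrix_effect = unname(me[[matrix]][a$name] %||% 1),
                   recovery = unname(re[[matrix]][a$name] %||% 1),
                   range = a$calibration_range)
  })
  # analytes outside the bundled six get neutral m = r = 1 via the %||% above;
  # names() are inherited from panel$analytes
  out
}

lognormal_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))   # mean exactly 1
}

set_scale <- function(model, set_kind) {
  switch(set_kind,
         neat = 1,
         post_spike = model$matrix_effect,
         pre_spike = ,
         routine = model$matrix_effect * model$recovery,
         tq_error(sprintf("unknown set kind '%s'", set_kind), class = "tq_usage_error"))
}

#' Simulate a response ratio
#'
#' @param conc Nominal concentration(s), >= 0.
#' @param model A `response_model`.
#' @param set_kind `"routine"` (default), `"neat"`, `"post_spike"` or
#'   `"pre_spike"` — see [response_model()] for the applied scale.
#' @param seed Optional integer; when given, draws are made under this seed
#'   without disturbing the caller's RNG state. When `NULL` the current RNG
#'   stream is used (callers such as [generate_calibration_set()] seed once).
#' @return Simulated response ratio(s).
#' @export
simulate_response <- function(conc, model,
                              set_kind = c("routine", "neat", "post_spike", "pre_spike"),
                              seed = NULL) {
  set_kind <- match.arg(set_kind)
  tq_check(inherits(model, "response_model"), "model must be a response_model",
           class = "tq_usage_error")
  tq_check(is.numeric(conc) && all(conc >= 0), "concentration must be >= 0",
           class = "tq_invalid_input")
  s <- set_scale(model, set_kind)
  mu <- s * (model$a2 * conc^2 + model$a1 * conc + model$a0)
  draw <- function() mu * lognormal_factor(length(conc), model$noise_cv)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

IS_HEIGHT <- 1e5   # fixed synthetic internal-standard height; ratios carry the noise

new_peak_table <- function(df) {
  cols <- peak_table_columns()
  for (m in setdiff(cols, names(df))) df[[m]] <- NA
  df <- df[cols]
  class(df) <- c("peak_table", "data.frame")
  df
}

#' Column contract of a peak table
#' @return Character vector of the required column names.
#' @export
peak_table_columns <- function() {
  c("sample_id", "analyte", "matrix", "role", "transition_role",
    "peak_height", "is_height", "nominal_conc", "day", "aliquot_index")
}

geometric_levels <- function(low, high, n) exp(seq(log(low), log(high), length.out = n))

peak_rows <- function(sample_id, analyte_obj, conc, ratio_q, model, set_kind,
                      matrix, role, day = NA_real_, aliquot_index = NA_integer_) {
  # qualifier response: expected ion ratio times an independent noisy response
  ratio_qual <- analyte_obj$ion_ratio *
    simulate_response(conc, model, set_kind)
  data.frame(sample_id = sample_id, analyte = analyte_obj$name, matrix = matrix,
             role = role,
             transition_role = c("quantifier", "qualifier"),
             peak_height = c(ratio_q, ratio_qual) * IS_HEIGHT,
             is_height = IS_HEIGHT,
             nominal_conc = conc, day = day, aliquot_index = aliquot_index,
             stringsAsFactors = FALSE)
}

#' Generate a calibration peak table
#'
#' Calibrators are geometrically spaced over each analyte's calibration
#' range (endpoints included) and pass through the full sample-preparation
#' response scale (`set_kind = "routine"`), so a curve fitted on them and
#' used for back-calculation cancels matrix effect and recovery — as in the
#' real assay, where calibrators are matrix-matched spikes.
#'
#' @param panel An `analyte_panel`.
#' @param n_levels Number of calibration levels, >= 3 (default 7).
#' @param replicates Replicates per level.
#' @param models Named list of `response_model`s per analyte.
#' @param matrix `"blood"` or `"faeces"`.
#' @param seed Integer seed.
#' @return A `peak_table` data frame with `role = "calibrator"`.
#' @export
generate_calibration_set <- function(panel, n_levels = 7, replicates = 1,
                                     models = default_response_models(panel, matrix),
                                     matrix = "blood", seed = 1) {
  if (n_levels < 3) {
    tq_error("a calibration series needs at least 3 levels", class = "tq_usage_error")
  }
  tq_check(replicates >= 1, "replicates must be >= 1")
  withr::with_seed(seed, {
    rows <- list()
    for (a in panel$analytes) {
      model <- models[[a$name]]
      levels <- geometric_levels(a$calibration_range[1], a$calibration_range[2], n_levels)
      for (i in seq_len(n_levels)) {
        for (r in seq_len(replicates)) {
          ratio <- simulate_response(levels[i], model, "routine")
          rows[[length(rows) + 1L]] <- peak_rows(
            sprintf("cal_%s_L%02d_R%02d", a$name, i, r), a, levels[i], ratio,
            model, "routine", matrix, "calibrator")
        }
      }
    }
    new_peak_table(do.call(rbind, rows))
  })
}

#' Default QC concentrations for an analyte
#'
#' Low = 3 x lowest calibrator, mid = geometric mid-range, high = 80% of
#' the top calibrator.
#'
#' @param analyte_obj An `analyte`.
#' @return Named numeric vector `c(low=, mid=, high=)`.
#' @export
qc_levels <- function(analyte_obj) {
  rng <- analyte_obj$calibration_range
  c(low = 3 * rng[1], mid = sqrt(prod(rng)), high = 0.8 * rng[2])
}

#' Generate a QC peak table for precision/bias studies
#'
#' Replicated QC samples at the [qc_levels()] concentrations across one or
#' more (pseudo-)days. A shared per-day lognormal factor with CV
#' `between_day_cv` models day-to-day drift on top of the instrument noise,
#' giving the two variance components the between-day precision estimator
#' decomposes.
#'
#' @inheritParams generate_calibration_set
#' @param n_days Number of days.
#' @param replicates Replicates per day and level.
#' @param between_day_cv CV of the shared per-day factor.
#' @return A `peak_table` with `role = "qc"` and `day` set.
#' @export
generate_qc_set <- function(panel, n_days = 1, replicates = 6,
                            models = default_response_models(panel, matrix),
                            between_day_cv = 0, matrix = "blood", seed = 1) {
  tq_check(n_days >= 1 && replicates >= 1, "n_days and replicates must be >= 1")
  withr::with_seed(seed, {
    rows <- list()
    for (a in panel$analytes) {
      model <- models[[a$name]]
      concs <- qc_levels(a)
      for (lv in names(concs)) {
        day_factor <- lognormal_factor(n_days, between_day_cv)
        for (d in seq_len(n_days)) {
          for (r in seq_len(replicates)) {
            ratio <- simulate_response(concs[[lv]], model, "routine") * day_factor[d]
            rows[[length(rows) + 1L]] <- peak_rows(
              sprintf("qc_%s_%s_D%02d_R%02d", a$name, lv, d, r), a, concs[[lv]],
              ratio, model, "routine", matrix, "qc", day = d)
          }
        }
      }
    }
    new_peak_table(do.call(rbind, rows))
  })
}

#' Generate the three-set matrix-effect/recovery experiment
#'
#' The post-extraction spike design: set A are neat standards, set B the
#' same concentrations spiked into blank matrix extracts after extraction,
#' set C spiked before extraction. Per-lot multiplicative effects (CV
#' `lot_cv`) are drawn once per lot and shared between the B and C records
#' of the same lot, so the matrix-effect and recovery estimators see
#' realistically paired lots.
#'
#' @inheritParams generate_calibration_set
#' @param n_lots Number of blank matrix lots, >= 2 (default 5).
#' @param levels Number of spike levels (1 or 2: the low and high
#'   [qc_levels()] concentrations).
#' @param lot_cv CV of the per-lot effect.
#' @return Named list of three `peak_table`s: `neat`, `post_spike`,
#'   `pre_spike` (roles `setA`, `setB`, `setC`).
#' @export
generate_matrix_experiment <- function(panel,
                                       models = default_response_models(panel, matrix),
                                       n_lots = 5, levels = 2, lot_cv = 0.10,
                                       matrix = "faeces", seed = 1) {
  if (n_lots < 2) tq_error("the matrix experiment needs >= 2 lots", class = "tq_usage_error")
  tq_check(levels %in% c(1L, 2L), "levels must be 1 or 2")
  withr::with_seed(seed, {
    sets <- list(neat = list(), post_spike = list(), pre_spike = list())
    role_of <- c(neat = "setA", post_spike = "setB", pre_spike = "setC")
    for (a in panel$analytes) {
      model <- models[[a$name]]
      concs <- qc_levels(a)[c("low", "high")][seq_len(levels)]
      lot_effect <- lognormal_factor(n_lots, lot_cv)
      for (lv in seq_along(concs)) {
        for (lot in seq_len(n_lots)) {
          for (kind in names(sets)) {
            ratio <- simulate_response(concs[[lv]], model, kind)
            if (kind != "neat") ratio <- ratio * lot_effect[lot]
            sets[[kind]][[length(sets[[kind]]) + 1L]] <- peak_rows(
              sprintf("mx_%s_%s_L%d_lot%02d", role_of[[kind]], a$name, lv, lot),
              a, concs[[lv]], ratio, model, kind, matrix, role_of[[kind]])
          }
        }
      }
    }
    lapply(sets, function(s) new_peak_table(do.call(rbind, s)))
  })
}

#' Biphasic pharmacokinetic profile of the poisoning case
#'
#' The true blood concentration is the two-compartment disposition curve
#' `C(t) = A_alpha * 2^(-t / t_half_alpha) + A_beta * 2^(-t / t_half_beta)`;
#' the faecal concentration is `faeces_scale * C(t) * (1 + bump(t))`, where
#' the optional Gaussian bump emulates the enterohepatic-recirculation
#' second peak around one month post-ingestion. The bump is generative
#' only: the estimators never model it — phase windows exclude it.
#'
#' Defaults encode the studied case: a fast distribution/elimination phase
#' of 1.8 days and a terminal phase of 81 days; blood near 12 ng/mL at the
#' first sampling (day 6) decaying through the 1.5 ng/mL LOQ shortly after
#' day 11; faecal levels `faeces_scale` times blood (the scale is not
#' identifiable from any paired mass-balance data and is a stated
#' convention); faecal aliquot RSD 25%.
#'
#' @param A_alpha,A_beta Phase amplitudes (ng/mL), >= 0.
#' @param t_half_alpha,t_half_beta Phase half-lives in days,
#'   `t_half_alpha < t_half_beta`.
#' @param faeces_scale Faeces-to-blood concentration ratio.
#' @param bump `NULL` or `list(center=, width=, height=)` (days, days,
#'   relative height) for the faecal second peak.
#' @param aliquot_rsd CV of the lognormal aliquot noise.
#' @param loq Limit of quantification applied to emitted values.
#' @return An object of class `pk_profile`.
#' @export
pk_profile <- function(A_alpha = 121, A_beta = 0.05,
                       t_half_alpha = 1.8, t_half_beta = 81,
                       faeces_scale = 2500,
                       bump = list(center = 32, width = 6, height = 0.8),
                       aliquot_rsd = 0.25, loq = 1.5) {
  tq_check(A_alpha >= 0 && A_beta >= 0, "amplitudes must be >= 0",
           class = "tq_invalid_input")
  tq_check(t_half_alpha > 0 && t_half_beta > 0 && t_half_alpha < t_half_beta,
           "half-lives must be positive with t_half_alpha < t_half_beta",
           class = "tq_invalid_input")
  tq_check(aliquot_rsd >= 0 && faeces_scale > 0 && loq > 0,
           "aliquot_rsd must be >= 0; faeces_scale and loq positive",
           class = "tq_invalid_input")
  if (!is.null(bump)) {
    tq_check(all(c("center", "width", "height") %in% names(bump)) &&
               bump$width > 0 && bump$height >= 0,
             "bump needs center, width > 0 and height >= 0",
             class = "tq_invalid_input")
  }
  structure(list(A_alpha = A_alpha, A_beta = A_beta,
                 t_half_alpha = t_half_alpha, t_half_beta = t_half_beta,
                 faeces_scale = faeces_scale, bump = bump,
                 aliquot_rsd = aliquot_rsd, loq = loq),
            class = "pk_profile")
}

#' True (noiseless) concentration of a profile
#'
#' @param profile A `pk_profile`.
#' @param t Days post-ingestion.
#' @param matrix `"blood"` or `"faeces"`.
#' @return Concentration(s) in ng/mL or ng/g.
#' @export
pk_true_conc <- function(profile, t, matrix = c("blood", "faeces")) {
  matrix <- match.arg(matrix)
  ct <- profile$A_alpha * 2^(-t / profile$t_half_alpha) +
    profile$A_beta * 2^(-t / profile$t_half_beta)
  if (matrix == "faeces") {
    b <- profile$bump
    f <- if (is.null(b)) 1 else 1 + b$height * exp(-((t - b$center) / b$width)^2)
    ct <- profile$faeces_scale * ct * f
  }
  ct
}

#' The case sampling schedule
#'
#' Days post-ingestion on which blood and faeces were sampled.
#' @return Integer vector of 16 days, day 6 through day 513.
#' @export
case_schedule <- function() c(6, 7, 11, 18, 22, 24, 32, 39, 50, 64, 93, 121, 204, 422, 470, 513)

#' Generate a synthetic concentration-time series pair
#'
#' Blood is sampled once per day; faeces as `n_aliquots` parallel aliquots
#' per day. Aliquot values are lognormal around the true curve with CV
#' `aliquot_rsd` (mean preserved). Values below the LOQ are emitted but
#' flagged censored, never dropped. Per-day aggregates are the arithmetic
#' mean of the quantified aliquots with their relative standard deviation.
#'
#' @param profile A [pk_profile()].
#' @param schedule Strictly increasing positive sampling days.
#' @param n_aliquots Either a single count or a set (default `3:6`) from
#'   which the per-day number of faecal aliquots is drawn.
#' @param analyte Analyte label carried on the series.
#' @param seed Integer seed.
#' @return List with `blood` and `faeces`, each a [conc_series()] whose
#'   `aliquots` data frame retains the raw values, plus the `profile`.
#' @export
generate_case_profile <- function(profile, schedule = case_schedule(),
                                  n_aliquots = 3:6, analyte = "coumatetralyl",
                                  seed = 1) {
  tq_check(inherits(profile, "pk_profile"), "profile must be a pk_profile",
           class = "tq_usage_error")
  if (length(schedule) < 2 || any(diff(schedule) <= 0) || any(schedule <= 0)) {
    tq_error("schedule must be strictly increasing positive days",
             class = "tq_usage_error")
  }
  tq_check(all(n_aliquots >= 1), "n_aliquots must be >= 1")
  withr::with_seed(seed, {
    one_matrix <- function(matrix, n_per_day) {
      ali <- do.call(rbind, lapply(seq_along(schedule), function(j) {
        n <- n_per_day[j]
        truth <- pk_true_conc(profile, schedule[j], matrix)
        vals <- truth * lognormal_factor(n, profile$aliquot_rsd)
        data.frame(matrix = matrix, analyte = analyte, day = schedule[j],
                   aliquot_index = seq_len(n), value = vals,
                   censored = vals < profile$loq, stringsAsFactors = FALSE)
      }))
      aggregate_conc_aliquots(ali, matrix = matrix, analyte = analyte,
                              loq = profile$loq)
    }
    n_blood <- rep(1L, length(schedule))
    n_faeces <- if (length(n_aliquots) == 1L) rep(as.integer(n_aliquots), length(schedule))
                else sample(as.integer(n_aliquots), length(schedule), replace = TRUE)
    list(blood = one_matrix("blood", n_blood),
         faeces = one_matrix("faeces", n_faeces),
         profile = profile)
  })
}

# Aggregate raw aliquot concentrations (numeric scale, no curve involved)
# into a conc_series: mean and RSD over quantified aliquots per day.
aggregate_conc_aliquots <- function(aliquots, matrix, analyte, loq) {
  pts <- do.call(rbind, lapply(split(aliquots, aliquots$day), function(d) {
    q <- d$value[!d$censored]
    conc <- if (length(q)) mean(q) else NA_real_
    data.frame(day = d$day[1],
               concentration = conc,
               censoring = if (length(q)) "quantified" else
                 if (any(d$value > 0)) "below_loq_detected" else "not_detected",
               n_aliquots = nrow(d),
               n_censored = sum(d$censored),
               aliquot_rsd = if (length(q) >= 2) 100 * stats::sd(q) / mean(q) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  pts <- pts[order(pts$day), , drop = FALSE]
  conc_series(pts, matrix = matrix, analyte = analyte, loq = loq,
              aliquots = aliquots)
}
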