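#' Analyte panel: compounds, transitions, units
#'
#' The panel is the domain model of the assay: which compounds are measured,
#' by which multiple-reaction-monitoring (MRM) transitions, over which
#' calibration range, and with which molar mass for unit conversion between
#' molar (uM) and mass-based (ng/mL blood, ng/g faeces dry matter)
#' concentrations. A bundled six-compound anticoagulant-rodenticide panel
#' (`default_panel()`) covers coumatetralyl, bromadiolone, difenacoum,
#' flocoumafen, brodifacoum and difethialone with warfarin-d5 as internal
#' standard.
#'
#' @name panel
NULL

#' Construct an MRM transition
#'
#' @param precursor_mz Precursor ion m/z. Must exceed `product_mz`.
#' @param product_mz Product ion m/z, positive.
#' @param role `"quantifier"` (drives quantification) or `"qualifier"`
#'   (confirms identity through the ion ratio).
#' @param cone_voltage Cone voltage in V (metadata).
#' @param collision_energy Collision energy in eV (metadata).
#' @return An object of class `mrm_transition`.
#' @export
mrm_transition <- function(precursor_mz, product_mz,
                           role = c("quantifier", "qualifier"),
                           cone_voltage = NA_real_, collision_energy = NA_real_) {
  role <- match.arg(role)
  tq_check(is.numeric(precursor_mz) && is.numeric(product_mz) &&
             precursor_mz > product_mz && product_mz > 0,
           "an MRM transition requires precursor_mz > product_mz > 0",
           class = "tq_invalid_panel")
  structure(
    list(precursor_mz = precursor_mz, product_mz = product_mz, role = role,
         cone_voltage = cone_voltage, collision_energy = collision_energy),
    class = "mrm_transition")
}

#' Construct an analyte definition
#'
#' An analyte carries its MRM transitions (exactly one quantifier), its
#' calibration range in mass units and, optionally, the same range in uM.
#' When both ranges are given they must agree through the molar mass to
#' within 1% after endpoint rounding (see [round_endpoint()]).
#'
#' @param name Unique analyte identifier.
#' @param molar_mass Average molecular weight in g/mol, positive.
#' @param transitions List of [mrm_transition()] objects.
#' @param calibration_range Numeric length-2, `(low, high)` in ng/mL or ng/g,
#'   `0 < low < high`.
#' @param calibration_range_molar Optional numeric length-2 in uM.
#' @param molecular_formula,retention_time Metadata.
#' @param ion_ratio Expected qualifier/quantifier response ratio used by the
#'   synthetic generator and as fallback for ion-ratio QC.
#' @return An object of class `analyte`.
#' @export
analyte <- function(name, molar_mass, transitions, calibration_range,
                    calibration_range_molar = NULL,
                    molecular_formula = NA_character_,
                    retention_time = NA_real_, ion_ratio = NA_real_) {
  tq_check(is.character(name) && nzchar(name), "analyte name must be a non-empty string",
           class = "tq_invalid_panel")
  if (!is.numeric(molar_mass) || length(molar_mass) != 1L || !is.finite(molar_mass) ||
      molar_mass <= 0) {
    tq_error(sprintf("analyte '%s': molar mass must be a positive number", name),
             class = "tq_invalid_panel")
  }
  tq_check(is.list(transitions) && length(transitions) >= 1L &&
             all(vapply(transitions, inherits, logical(1), "mrm_transition")),
           sprintf("analyte '%s': transitions must be a list of mrm_transition objects", name),
           class = "tq_invalid_panel")
  roles <- vapply(transitions, `[[`, character(1), "role")
  if (sum(roles == "quantifier") != 1L) {
    tq_error(sprintf("analyte '%s': exactly one quantifier transition required, found %d",
                     name, sum(roles == "quantifier")),
             class = "tq_invalid_panel")
  }
  tq_check(is.numeric(calibration_range) && length(calibration_range) == 2L &&
             all(calibration_range > 0) && calibration_range[1] < calibration_range[2],
           sprintf("analyte '%s': calibration range must satisfy 0 < low < high", name),
           class = "tq_invalid_panel")
  if (!is.null(calibration_range_molar)) {
    tq_check(is.numeric(calibration_range_molar) && length(calibration_range_molar) == 2L &&
               all(calibration_range_molar > 0) &&
               calibration_range_molar[1] < calibration_range_molar[2],
             sprintf("analyte '%s': molar calibration range must satisfy 0 < low < high", name),
             class = "tq_invalid_panel")
    implied <- round_endpoint(convert_concentration(calibration_range_molar, "uM", "ng/mL",
                                                    molar_mass))
    rel <- abs(implied - calibration_range) / calibration_range
    if (any(rel > 0.01)) {
      tq_error(sprintf(
        "analyte '%s': mass and molar calibration ranges disagree by more than 1%% (stated %g-%g, implied %g-%g ng/mL)",
        name, calibration_range[1], calibration_range[2], implied[1], implied[2]),
        class = "tq_invalid_panel")
    }
  }
  structure(
    list(name = name, molecular_formula = molecular_formula, molar_mass = molar_mass,
         retention_time = retention_time, transitions = transitions,
         calibration_range = unname(calibration_range),
         calibration_range_molar = if (is.null(calibration_range_molar)) NULL else
           unname(calibration_range_molar),
         ion_ratio = ion_ratio),
    class = "analyte")
}

#' @export
print.analyte <- function(x, ...) {
  q <- quantifier_transition(x)
  cat(sprintf("<analyte> %s (%.2f g/mol, RT %.2f min)\n", x$name, x$molar_mass,
              x$retention_time))
  cat(sprintf("  quantifier %.1f > %.1f; range %g-%g ng/mL|ng/g\n",
              q$precursor_mz, q$product_mz,
              x$calibration_range[1], x$calibration_range[2]))
  invisible(x)
}

#' Quantifier / qualifier transitions of an analyte
#' @param x An `analyte`.
#' @return The quantifier `mrm_transition`, or list of qualifier transitions.
#' @export
quantifier_transition <- function(x) {
  roles <- vapply(x$transitions, `[[`, character(1), "role")
  x$transitions[[which(roles == "quantifier")]]
}

#' @rdname quantifier_transition
#' @export
qualifier_transitions <- function(x) {
  roles <- vapply(x$transitions, `[[`, character(1), "role")
  x$transitions[roles == "qualifier"]
}

#' Assemble an analyte panel
#'
#' @param analytes List of [analyte()] objects with unique names.
#' @param internal_standard Analyte-like record for the internal standard
#'   (isotope-labelled; here warfarin-d5), distinct from all analytes. A
#'   `working_concentration` in mg/L may be attached as metadata.
#' @param name Panel identifier.
#' @return An object of class `analyte_panel`.
#' @export
analyte_panel <- function(analytes, internal_standard, name = "panel") {
  tq_check(is.list(analytes) && length(analytes) >= 1L &&
             all(vapply(analytes, inherits, logical(1), "analyte")),
           "analytes must be a list of analyte objects", class = "tq_invalid_panel")
  nms <- vapply(analytes, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    tq_error(sprintf("duplicate analyte name(s): %s",
                     paste(unique(nms[duplicated(nms)]), collapse = ", ")),
             class = "tq_invalid_panel")
  }
  tq_check(is.list(internal_standard) && !is.null(internal_standard$name),
           "internal_standard must carry at least a name", class = "tq_invalid_panel")
  if (internal_standard$name %in% nms) {
    tq_error("internal standard must be distinct from the analytes",
             class = "tq_invalid_panel")
  }
  names(analytes) <- nms
  structure(list(name = name, analytes = analytes,
                 internal_standard = internal_standard),
            class = "analyte_panel")
}

#' @export
print.analyte_panel <- function(x, ...) {
  cat(sprintf("<analyte_panel> %s: %d analytes, IS = %s\n",
              x$name, length(x$analytes), x$internal_standard$name))
  for (a in x$analytes) {
    q <- quantifier_transition(a)
    cat(sprintf("  %-14s %6.1f > %5.1f   %8g-%g ng/mL|ng/g\n", a$name,
                q$precursor_mz, q$product_mz,
                a$calibration_range[1], a$calibration_range[2]))
  }
  invisible(x)
}

#' Analyte names of a panel
#' @param panel An `analyte_panel`.
#' @export
panel_analytes <- function(panel) {
  vapply(panel$analytes, `[[`, character(1), "name")
}

#' Convert between molar and mass concentration units
#'
#' Since 1 uM x 1 g/mol = 1 ng/mL, the mass-basis value is `uM * molar_mass`.
#' `ng/mL` (blood) and `ng/g` (faeces dry matter) are treated as the same
#' numeric scale tagged by matrix: calibrators are prepared against the same
#' masses in both matrices and no density correction is applied.
#'
#' @param value Non-negative concentration value(s).
#' @param from,to One of `"uM"`, `"ng/mL"`, `"ng/g"` (`"µM"` accepted).
#' @param molar_mass Molar mass in g/mol, positive.
#' @return Converted concentration, same length as `value`.
#' @examples
#' convert_concentration(2.5, "uM", "ng/mL", 292.33)   # 730.8 (coumatetralyl)
#' @export
convert_concentration <- function(value, from, to, molar_mass) {
  norm <- function(u) {
    u <- sub("µ", "u", u)
    if (!u %in% c("uM", "ng/mL", "ng/g"))
      tq_error(sprintf("unknown concentration unit '%s' (use uM, ng/mL or ng/g)", u),
               class = "tq_usage_error")
    if (u == "ng/g") "ng/mL" else u   # mass units share one numeric scale
  }
  from <- norm(from); to <- norm(to)
  tq_check(is.numeric(value) && all(value >= 0, na.rm = TRUE),
           "concentration values must be non-negative", class = "tq_invalid_input")
  if (!is.numeric(molar_mass) || length(molar_mass) != 1L || !is.finite(molar_mass) ||
      molar_mass <= 0) {
    tq_error("molar mass must be a positive number", class = "tq_invalid_panel")
  }
  if (from == to) return(value)
  if (from == "uM") value * molar_mass else value / molar_mass
}

#' Round a calibration endpoint for reporting
#'
#' Reporting convention for printed range endpoints: half-up to an integer
#' at or above 100, half-up to one decimal below 10, half-up to an integer
#' in between.
#'
#' @param x Numeric vector.
#' @return Rounded values.
#' @export
round_endpoint <- function(x) {
  half_up <- function(v, digits) floor(v * 10^digits + 0.5) / 10^digits
  ifelse(x < 10, half_up(x, 1L), half_up(x, 0L))
}

one_transition <- function(rec) {
  mrm_transition(precursor_mz = as.numeric(rec$precursor_mz),
                 product_mz = as.numeric(rec$product_mz),
                 role = as.character(rec$role),
                 cone_voltage = as.numeric(rec$cone_voltage %||% NA_real_),
                 collision_energy = as.numeric(rec$collision_energy %||% NA_real_))
}

#' Load and validate a panel configuration
#'
#' Reads a YAML or JSON panel definition (see
#' `system.file("extdata/panels/rodenticides6.yaml", package = "toxiquant")`
#' for the schema) and returns a validated [analyte_panel()]. All analyte
#' invariants are enforced: unique names, exactly one quantifier transition,
#' positive ordered calibration ranges, and agreement between mass and molar
#' ranges through the molar mass within 1%.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` panel file.
#' @return An `analyte_panel`.
#' @export
load_panel <- function(path) {
  tq_check(file.exists(path), sprintf("panel config '%s' not found", path),
           class = "tq_usage_error")
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    tq_error("panel config must be a .yaml/.yml or .json file", class = "tq_usage_error")
  }
  tq_check(!is.null(cfg$analytes) && length(cfg$analytes) > 0,
           "panel config carries no analytes", class = "tq_invalid_panel")
  build_analyte <- function(a) {
    analyte(name = as.character(a$name),
            molar_mass = as.numeric(a$molar_mass %||% NA_real_),
            transitions = lapply(a$transitions, one_transition),
            calibration_range = as.numeric(unlist(a$calibration_range)),
            calibration_range_molar = if (is.null(a$calibration_range_molar)) NULL else
              as.numeric(unlist(a$calibration_range_molar)),
            molecular_formula = as.character(a$molecular_formula %||% NA_character_),
            retention_time = as.numeric(a$retention_time %||% NA_real_),
            ion_ratio = as.numeric(a$ion_ratio %||% NA_real_))
  }
  analytes <- lapply(cfg$analytes, build_analyte)
  is_cfg <- cfg$internal_standard
  tq_check(!is.null(is_cfg), "panel config needs an internal_standard entry",
           class = "tq_invalid_panel")
  internal_standard <- list(
    name = as.character(is_cfg$name),
    molecular_formula = as.character(is_cfg$molecular_formula %||% NA_character_),
    molar_mass = as.numeric(is_cfg$molar_mass %||% NA_real_),
    retention_time = as.numeric(is_cfg$retention_time %||% NA_real_),
    working_concentration = as.numeric(is_cfg$working_concentration_mg_per_L %||% NA_real_),
    transitions = lapply(is_cfg$transitions %||% list(), one_transition))
  analyte_panel(analytes, internal_standard,
                name = as.character(cfg$name %||% "panel"))
}

#' The bundled six-compound rodenticide panel
#'
#' Transitions, retention times, molar masses and calibration ranges for
#' coumatetralyl, bromadiolone, difenacoum, flocoumafen, brodifacoum and
#' difethialone with warfarin-d5 as internal standard.
#'
#' @return An `analyte_panel`.
#' @export
default_panel <- function() {
  load_panel(system.file("extdata", "panels", "rodenticides6.yaml",
                         package = "toxiquant", mustWork = TRUE))
}
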