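# Canonical 5-year age bands used for incidence reporting; the open upper band
# "85+" applies to every age >= 85.
AGE_BANDS <- c("40-44", "45-49", "50-54", "55-59", "60-64",
               "65-69", "70-74", "75-79", "80-84", "85+")

STAGES <- c("I", "II", "III", "IV")

# Baseline incidence of invasive breast cancer in the general female urban
# Chinese population, per woman per year, by 5-year band (cancer-registry
# reporting convention).
DEFAULT_INCIDENCE <- c(
  "40-44" = 0.0006100, "45-49" = 0.0010056, "50-54" = 0.0011650,
  "55-59" = 0.0011179, "60-64" = 0.0010458, "65-69" = 0.0009782,
  "70-74" = 0.0009912, "75-79" = 0.0009067, "80-84" = 0.0007803,
  "85+"   = 0.0006430
)

rng3 <- function(baseline, min = NA_real_, max = NA_real_) {
  c(baseline = baseline, min = min, max = max)
}

#' Construct and validate the full model parameter set
#'
#' Assembles every quantity the screening model uses: age-specific invasive
#' incidence, the DCIS-to-invasive incidence ratio, relative risks, annual
#' stage progression probabilities, stage-specific symptom probabilities
#' (obtained by calibration, see [calibrate_symptom_probs()]), post-treatment
#' fatality, screening test performance per modality combination, utility
#' scores, the false-positive disutility, unit costs in 2014 US$, the annual
#' discount rate and the willingness-to-pay threshold.
#'
#' Defaults are the programme's baseline values. Quantities that carry an
#' uncertainty range (test performance, utilities, disutility, costs) are
#' stored as `c(baseline, min, max)` triples and are exactly the parameters
#' varied in sensitivity analyses; quantities without a range (incidence,
#' progression, symptom, fatality probabilities) are treated as fixed.
#'
#' @param incidence_by_age named numeric, annual invasive onset probability per
#'   5-year band `"40-44"` ... `"85+"` (general population).
#' @param dcis_ratio ratio of DCIS incidence to invasive incidence.
#' @param rr_dcis_to_invasive relative risk of invasive cancer given DCIS.
#' @param rr_high_risk relative risk of onset in the modelled high-risk cohort
#'   versus the general population.
#' @param progression named numeric: annual probabilities `I_II`, `II_III`,
#'   `III_IV` of stage progression and `IV_death` of breast-cancer death at
#'   stage IV (untreated).
#' @param symptom_prob named numeric, per-stage annual probability of
#'   symptomatic presentation, stages I-IV.
#' @param fatality_treated named numeric, per-stage annual breast-cancer
#'   fatality probability after treatment, stages I-IV.
#' @param test_perf named list of modality combinations; each element holds
#'   `sensitivity` and `specificity` triples. The defaults describe
#'   `us_then_mammo` (ultrasound with mammography follow-up, used at ages
#'   40-44) and `us_plus_mammo` (ultrasound and mammography together, ages
#'   45-69). Extra combinations (e.g. `mammo_alone`) may be supplied.
#' @param utility named list of per-stage utility triples, stages I-IV.
#' @param disutility_fp triple: fractional utility decrement experienced
#'   during a false-positive episode.
#' @param fp_duration_years duration of the false-positive utility decrement,
#'   in years. The default is a five-week episode (`5/52.18`), covering recall,
#'   biopsy and the wait for a benign result; the QALY loss per episode is
#'   `disutility_fp * fp_duration_years`.
#' @param costs named list: `questionnaire`, `screening`, `biopsy` triples and
#'   a `treatment` list of one-time costs per stage `DCIS`, `I`-`IV`
#'   (2014 US$).
#' @param discount_rate annual discount rate applied to costs and QALYs.
#' @param wtp_threshold willingness-to-pay, US$ per QALY.
#' @param high_risk_comparator logical; if `TRUE` (default) the no-screening
#'   comparator cohort is the same high-risk cohort (`rr_high_risk` applies to
#'   both arms); if `FALSE`, comparisons built by [run_scenarios()] use a
#'   general-population comparator.
#' @return a validated object of class `bc_parameters`.
#' @export
bc_parameters <- function(incidence_by_age = DEFAULT_INCIDENCE,
                          dcis_ratio = 0.12,
                          rr_dcis_to_invasive = 2.02,
                          rr_high_risk = 2,
                          progression = c(I_II = 0.06, II_III = 0.11,
                                          III_IV = 0.15, IV_death = 0.23),
                          symptom_prob = c(I = 0.004, II = 0.014,
                                           III = 0.380, IV = 0.980),
                          fatality_treated = c(I = 0.006, II = 0.042,
                                               III = 0.093, IV = 0.275),
                          test_perf = list(
                            us_then_mammo = list(
                              sensitivity = rng3(0.848, 0.681, 0.949),
                              specificity = rng3(0.994, 0.990, 0.996)),
                            us_plus_mammo = list(
                              sensitivity = rng3(0.939, 0.798, 0.993),
                              specificity = rng3(0.980, 0.975, 0.985))),
                          utility = list(
                            I   = rng3(0.79, 0.77, 0.80),
                            II  = rng3(0.79, 0.78, 0.80),
                            III = rng3(0.77, 0.76, 0.79),
                            IV  = rng3(0.69, 0.65, 0.72)),
                          disutility_fp = rng3(0.25, 0.11, 0.34),
                          fp_duration_years = 5 / 52.18,
                          costs = list(
                            questionnaire = rng3(1.6, 1.1, 2.1),
                            screening     = rng3(85.5, 59.8, 111.1),
                            biopsy        = rng3(45.6, 31.0, 59.3),
                            treatment = list(
                              DCIS = rng3(2435, 1705, 3166),
                              I    = rng3(10067, 7047, 13087),
                              II   = rng3(11068, 7748, 14388),
                              III  = rng3(12867, 9007, 16727),
                              IV   = rng3(17766, 12436, 23096))),
                          discount_rate = 0.03,
                          wtp_threshold = 23050,
                          high_risk_comparator = TRUE) {
  p <- structure(list(
    incidence_by_age = incidence_by_age,
    dcis_ratio = dcis_ratio,
    rr_dcis_to_invasive = rr_dcis_to_invasive,
    rr_high_risk = rr_high_risk,
    progression = progression,
    symptom_prob = symptom_prob,
    fatality_treated = fatality_treated,
    test_perf = test_perf,
    utility = utility,
    disutility_fp = disutility_fp,
    fp_duration_years = fp_duration_years,
    costs = costs,
    discount_rate = discount_rate,
    wtp_threshold = wtp_threshold,
    high_risk_comparator = isTRUE(high_risk_comparator),
    age_max = 100L
  ), class = "bc_parameters")
  validate_parameters(p)
}

check_prob <- function(x, path) {
  bad <- !is.finite(x) | x < 0 | x > 1
  if (any(bad)) {
    stop(sprintf("validation error at '%s': value %s outside [0, 1]",
                 path, paste(x[bad], collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

check_triple <- function(x, path, prob = FALSE) {
  if (!all(c("baseline", "min", "max") %in% names(x))) {
    stop(sprintf("configuration error: '%s' must have baseline/min/max", path),
         call. = FALSE)
  }
  if (prob) check_prob(x[["baseline"]], path)
  if (!is.na(x[["min"]]) && !is.na(x[["max"]])) {
    if (x[["min"]] > x[["baseline"]] || x[["baseline"]] > x[["max"]]) {
      stop(sprintf("validation error at '%s': need min <= baseline <= max", path),
           call. = FALSE)
    }
    if (prob) check_prob(c(x[["min"]], x[["max"]]), path)
    if (!prob && x[["min"]] < 0) {
      stop(sprintf("validation error at '%s': negative cost", path), call. = FALSE)
    }
  }
  if (!prob && x[["baseline"]] < 0) {
    stop(sprintf("validation error at '%s': negative cost", path), call. = FALSE)
  }
  invisible(x)
}

validate_parameters <- function(p) {
  stopifnot(inherits(p, "bc_parameters"))
  missing_bands <- setdiff(AGE_BANDS, names(p$incidence_by_age))
  if (length(missing_bands)) {
    stop("configuration error: incidence_by_age missing band(s): ",
         paste(missing_bands, collapse = ", "), call. = FALSE)
  }
  check_prob(p$incidence_by_age, "incidence_by_age")
  check_prob(p$dcis_ratio, "dcis_ratio")
  if (!is.finite(p$rr_high_risk) || p$rr_high_risk <= 0) {
    stop("validation error at 'rr_high_risk': must be > 0", call. = FALSE)
  }
  if (!is.finite(p$rr_dcis_to_invasive) || p$rr_dcis_to_invasive <= 0) {
    stop("validation error at 'rr_dcis_to_invasive': must be > 0", call. = FALSE)
  }
  for (nm in c("I_II", "II_III", "III_IV", "IV_death")) {
    if (!nm %in% names(p$progression)) {
      stop("configuration error: progression missing key '", nm, "'", call. = FALSE)
    }
  }
  check_prob(p$progression, "progression")
  for (nm in STAGES) {
    if (!nm %in% names(p$symptom_prob)) {
      stop("configuration error: symptom_prob missing stage '", nm, "'", call. = FALSE)
    }
    if (!nm %in% names(p$fatality_treated)) {
      stop("configuration error: fatality_treated missing stage '", nm, "'",
           call. = FALSE)
    }
    check_triple(p$utility[[nm]], paste0("utility.", nm), prob = TRUE)
  }
  check_prob(p$symptom_prob, "symptom_prob")
  check_prob(p$fatality_treated, "fatality_treated")
  for (combo in names(p$test_perf)) {
    check_triple(p$test_perf[[combo]]$sensitivity,
                 paste0("test_perf.", combo, ".sensitivity"), prob = TRUE)
    check_triple(p$test_perf[[combo]]$specificity,
                 paste0("test_perf.", combo, ".specificity"), prob = TRUE)
  }
  check_triple(p$disutility_fp, "disutility_fp", prob = TRUE)
  check_prob(p$fp_duration_years, "fp_duration_years")
  for (nm in c("questionnaire", "screening", "biopsy")) {
    check_triple(p$costs[[nm]], paste0("costs.", nm))
  }
  for (nm in c("DCIS", STAGES)) {
    check_triple(p$costs$treatment[[nm]], paste0("costs.treatment.", nm))
  }
  if (!is.finite(p$discount_rate) || p$discount_rate < 0) {
    stop("validation error at 'discount_rate': must be >= 0", call. = FALSE)
  }
  p
}

#' Load model parameters from a YAML or JSON configuration
#'
#' Keys omitted from the configuration fall back to the baseline defaults of
#' [bc_parameters()]. The bundled `params_table1.yaml`
#' (`system.file("extdata", "params_table1.yaml", package = "bcscreen")`)
#' spells out every baseline value explicitly.
#'
#' @param config_source path to a `.yaml`/`.yml`/`.json` file, or a named list
#'   already in configuration shape.
#' @return a validated `bc_parameters` object.
#' @export
load_parameters <- function(config_source) {
  cfg <- if (is.character(config_source)) {
    if (!file.exists(config_source)) {
      stop("configuration error: file not found: ", config_source, call. = FALSE)
    }
    if (grepl("\\.json$", config_source, ignore.case = TRUE)) {
      jsonlite::read_json(config_source, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config_source)
    }
  } else if (is.list(config_source)) {
    config_source
  } else {
    stop("configuration error: config_source must be a path or a list",
         call. = FALSE)
  }
  defaults <- unclass(bc_parameters())
  merged <- modify_list_deep(defaults, cfg)
  # named vectors arrive from YAML as lists; coerce the flat numeric blocks
  for (nm in c("incidence_by_age", "progression", "symptom_prob",
               "fatality_treated")) {
    merged[[nm]] <- unlist(merged[[nm]])
  }
  merged$disutility_fp <- unlist(merged$disutility_fp)
  for (combo in names(merged$test_perf)) {
    merged$test_perf[[combo]] <- lapply(merged$test_perf[[combo]], unlist)
  }
  merged$utility <- lapply(merged$utility, unlist)
  for (nm in c("questionnaire", "screening", "biopsy")) {
    merged$costs[[nm]] <- unlist(merged$costs[[nm]])
  }
  merged$costs$treatment <- lapply(merged$costs$treatment, unlist)
  do.call(bc_parameters, merged[setdiff(names(merged), "age_max")])
}

modify_list_deep <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- modify_list_deep(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Serialize parameters back to configuration shape
#'
#' Inverse of [load_parameters()]: `load_parameters(serialize_parameters(p))`
#' reproduces `p`.
#'
#' @param params a `bc_parameters` object.
#' @param file optional path; when given, written as YAML.
#' @return the configuration list, invisibly when `file` is given.
#' @export
serialize_parameters <- function(params, file = NULL) {
  stopifnot(inherits(params, "bc_parameters"))
  cfg <- unclass(params)
  cfg$age_max <- NULL
  cfg <- rapply(cfg, function(x) {
    if (!is.null(names(x))) as.list(x) else x
  }, classes = c("numeric", "integer"), how = "replace")
  if (!is.null(file)) {
    yaml::write_yaml(cfg, file, precision = 12)
    return(invisible(cfg))
  }
  cfg
}

#' @export
print.bc_parameters <- function(x, ...) {
  cat("<bc_parameters>\n")
  cat("  high-risk RR:", x$rr_high_risk,
      "| discount:", x$discount_rate,
      "| WTP:", x$wtp_threshold, "US$/QALY\n")
  cat("  progression (I-II, II-III, III-IV, IV-death):",
      paste(x$progression, collapse = ", "), "\n")
  cat("  symptom probabilities (I-IV):",
      paste(x$symptom_prob, collapse = ", "), "\n")
  cat("  modalities:", paste(names(x$test_perf), collapse = ", "), "\n")
  invisible(x)
}

age_band <- function(age) {
  ifelse(age >= 85, "85+",
         paste0(5 * (age %/% 5), "-", 5 * (age %/% 5) + 4))
}

#' Annual onset probability of a breast lesion at a given age
#'
#' Invasive onset is the general-population band incidence scaled by the
#' high-risk relative risk; DCIS onset is the invasive onset scaled by the
#' DCIS-to-invasive incidence ratio.
#'
#' @param age age in completed years, 40 to `age_max`.
#' @param params a `bc_parameters` object.
#' @param lesion `"invasive"` or `"dcis"`.
#' @return annual onset probability.
#' @export
onset_probability <- function(age, params, lesion = c("invasive", "dcis")) {
  lesion <- match.arg(lesion)
  if (any(age < 40)) {
    stop("domain error: onset_probability defined for ages >= 40", call. = FALSE)
  }
  if (any(age > params$age_max)) {
    stop("domain error: age exceeds model horizon (age_max = ",
         params$age_max, ")", call. = FALSE)
  }
  p <- unname(params$incidence_by_age[age_band(age)]) * params$rr_high_risk
  if (lesion == "dcis") p <- p * params$dcis_ratio
  pmin(p, 1)
}

#' Define a screening strategy
#'
#' @param name strategy label used in reports.
#' @param interval_years years between screening rounds; `0` disables
#'   screening entirely (the comparator arm).
#' @param age_range two integers, the eligible age range (inclusive).
#' @param modality_by_age_band named list mapping `"lo-hi"` age bands to a
#'   modality combination name present in `test_perf`. The default assigns
#'   ultrasound-with-mammography-follow-up to ages 40-44 and combined
#'   ultrasound-plus-mammography to ages 45-69.
#' @param treatment_uptake fraction of biopsy-confirmed cases that go on to
#'   treatment.
#' @return an object of class `bc_strategy`.
#' @export
bc_strategy <- function(name = "annual",
                        interval_years = 1,
                        age_range = c(40L, 69L),
                        modality_by_age_band = list(
                          "40-44" = "us_then_mammo",
                          "45-69" = "us_plus_mammo"),
                        treatment_uptake = 1.0) {
  if (length(interval_years) != 1 || interval_years < 0 ||
      interval_years != round(interval_years)) {
    stop("validation error: interval_years must be a non-negative integer",
         call. = FALSE)
  }
  if (treatment_uptake < 0 || treatment_uptake > 1) {
    stop("validation error: treatment_uptake must lie in [0, 1]", call. = FALSE)
  }
  if (interval_years > 0) {
    bands <- strategy_bands(modality_by_age_band)
    covered <- unlist(lapply(seq_len(nrow(bands)),
                             function(i) bands$lo[i]:bands$hi[i]))
    needed <- age_range[1]:age_range[2]
    if (!all(needed %in% covered)) {
      stop("validation error: modality bands do not tile the eligible age range",
           call. = FALSE)
    }
  }
  structure(list(
    name = name,
    interval_years = as.integer(interval_years),
    age_range = as.integer(age_range),
    modality_by_age_band = modality_by_age_band,
    treatment_uptake = treatment_uptake
  ), class = "bc_strategy")
}

strategy_bands <- function(modality_by_age_band) {
  parts <- strsplit(names(modality_by_age_band), "-", fixed = TRUE)
  data.frame(
    lo = vapply(parts, function(x) as.integer(x[1]), integer(1)),
    hi = vapply(parts, function(x) as.integer(x[2]), integer(1)),
    modality = unlist(modality_by_age_band, use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

#' The no-screening comparator strategy
#' @return a `bc_strategy` with screening disabled.
#' @export
no_screening <- function() {
  bc_strategy(name = "none", interval_years = 0,
              modality_by_age_band = list(), treatment_uptake = 1.0)
}

#' @export
print.bc_strategy <- function(x, ...) {
  if (x$interval_years == 0) {
    cat("<bc_strategy>", x$name, "(no screening)\n")
  } else {
    cat("<bc_strategy>", x$name, "| every", x$interval_years,
        "year(s), ages", paste(x$age_range, collapse = "-"),
        "| uptake", x$treatment_uptake, "\n")
  }
  invisible(x)
}

#' Build a life table of other-cause mortality
#'
#' @param age integer ages covered (must include the whole model horizon,
#'   40 to `age_max`, for use in [run_cohort()]).
#' @param qx annual probability of death from causes other than breast cancer
#'   at each age.
#' @return an object of class `bc_life_table`: a named numeric vector of
#'   annual probabilities indexed by age.
#' @export
bc_life_table <- function(age, qx) {
  if (length(age) != length(qx)) {
    stop("validation error: age and qx must have equal length", call. = FALSE)
  }
  check_prob(qx, "life table qx")
  structure(stats::setNames(as.numeric(qx), as.character(as.integer(age))),
            class = "bc_life_table")
}

lt_qx <- function(life_table, age) {
  q <- unname(life_table[as.character(as.integer(age))])
  if (any(is.na(q))) {
    stop("domain error: life table does not cover age ",
         paste(age[is.na(q)], collapse = ", "), call. = FALSE)
  }
  q
}

#' @export
print.bc_life_table <- function(x, ...) {
  ages <- as.integer(names(x))
  cat("<bc_life_table> ages", min(ages), "-", max(ages),
      "| q(40) =", signif(unname(x[as.character(min(ages))]), 3),
      "| q(", max(ages), ") =", signif(unname(x[as.character(max(ages))]), 3),
      "\n")
  invisible(x)
}
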