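#' Test performance for a woman's age under a strategy
#'
#' Maps the woman's age to the modality combination assigned to her age band
#' and returns that combination's baseline sensitivity and specificity.
#'
#' @param age age in completed years.
#' @param strategy a `bc_strategy`.
#' @param params a `bc_parameters` object.
#' @return a list with `sensitivity`, `specificity` and `modality`, or `NULL`
#'   when the age is outside the strategy's eligible range (a not-screened
#'   signal, not an error).
#' @export
test_characteristics <- function(age, strategy, params) {
  if (strategy$interval_years == 0) return(NULL)
  if (age < strategy$age_range[1] || age > strategy$age_range[2]) return(NULL)
  bands <- strategy_bands(strategy$modality_by_age_band)
  hit <- which(age >= bands$lo & age <= bands$hi)
  if (!length(hit)) return(NULL)
  combo <- bands$modality[hit[1]]
  perf <- params$test_perf[[combo]]
  if (is.null(perf)) {
    stop("configuration error: strategy refers to unknown modality '", combo,
         "'", call. = FALSE)
  }
  list(sensitivity = unname(perf$sensitivity[["baseline"]]),
       specificity = unname(perf$specificity[["baseline"]]),
       modality = combo)
}

screening_due <- function(age, strategy) {
  strategy$interval_years > 0 &&
    age >= strategy$age_range[1] && age <= strategy$age_range[2] &&
    (age - strategy$age_range[1]) %% strategy$interval_years == 0
}

#' Apply one screening round to a cohort occupancy vector
#'
#' Women in the healthy, DCIS and preclinical states attend. Every attendee
#' incurs the questionnaire and screening costs. Preclinical and DCIS disease
#' is detected with probability `sensitivity`; detected women incur the biopsy
#' cost and, with probability `treatment_uptake`, move to the treated state and
#' incur the one-time stage-specific treatment cost (invasive cases declining
#' treatment move to the diagnosed-untreated state; DCIS cases declining
#' treatment remain in the DCIS state). Disease-free women screen falsely
#' positive with probability `1 - specificity`, incurring the biopsy cost and
#' the false-positive utility decrement over the episode duration
#' (`disutility_fp * fp_duration_years` QALYs). Already-diagnosed and
#' treated women do not attend.
#'
#' @param occupancy numeric occupancy vector over [health_states()].
#' @param age age at this round.
#' @param strategy a `bc_strategy`.
#' @param params a `bc_parameters` object.
#' @return list: `occupancy` (updated, same total mass), `cost` (expected
#'   undiscounted cost increment per cohort member), `disutility` (expected
#'   QALY decrement for the cycle from false positives), `detected` (named
#'   vector of detection mass: DCIS, I-IV), `false_positives` (mass).
#' @export
apply_screening_round <- function(occupancy, age, strategy, params) {
  tc <- test_characteristics(age, strategy, params)
  if (is.null(tc)) {
    return(list(occupancy = occupancy, cost = 0, disutility = 0,
                detected = stats::setNames(numeric(5), c("DCIS", STAGES)),
                false_positives = 0))
  }
  total0 <- sum(occupancy)
  if (abs(total0 - sum(occupancy[c(S_BCDEATH, S_OCDEATH)]) -
          sum(occupancy[c(S_HEALTHY, S_DCIS, S_PRE, S_TDCIS, S_TREAT, S_DIAG)])) >
      1e-8 * max(1, total0)) {
    stop("internal consistency error: occupancy does not sum to surviving mass",
         call. = FALSE)
  }
  sens <- tc$sensitivity; spec <- tc$specificity
  uptake <- strategy$treatment_uptake
  attending <- sum(occupancy[c(S_HEALTHY, S_DCIS, S_PRE)])
  cost <- attending * (params$costs$questionnaire[["baseline"]] +
                       params$costs$screening[["baseline"]])

  fp <- occupancy[S_HEALTHY] * (1 - spec)
  cost <- cost + fp * params$costs$biopsy[["baseline"]]
  disutility <- fp * params$disutility_fp[["baseline"]] * params$fp_duration_years

  det_dcis <- occupancy[S_DCIS] * sens
  det_pre <- occupancy[S_PRE] * sens
  cost <- cost + (det_dcis + sum(det_pre)) * params$costs$biopsy[["baseline"]]

  treat_cost <- vapply(c("DCIS", STAGES),
                       function(s) params$costs$treatment[[s]][["baseline"]],
                       numeric(1))
  occupancy[S_DCIS] <- occupancy[S_DCIS] - det_dcis * uptake
  occupancy[S_TDCIS] <- occupancy[S_TDCIS] + det_dcis * uptake
  cost <- cost + det_dcis * uptake * treat_cost[["DCIS"]]

  occupancy[S_PRE] <- occupancy[S_PRE] - det_pre
  occupancy[S_TREAT] <- occupancy[S_TREAT] + det_pre * uptake
  occupancy[S_DIAG] <- occupancy[S_DIAG] + det_pre * (1 - uptake)
  cost <- cost + sum(det_pre * uptake * treat_cost[STAGES])

  detected <- stats::setNames(c(det_dcis * uptake, det_pre), c("DCIS", STAGES))
  list(occupancy = occupancy, cost = unname(cost),
       disutility = unname(disutility), detected = detected,
       false_positives = unname(fp))
}
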