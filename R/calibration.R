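#' Stage distribution of symptomatic presentations in an unscreened cohort
#'
#' Runs the cohort engine with screening disabled and tallies first
#' symptomatic presentations by stage over the lifetime horizon, normalised to
#' proportions. In an unscreened population cases surface only on symptoms, so
#' this distribution is the model's analogue of the registry stage
#' distribution at diagnosis — a joint consequence of the progression rates
#' and the per-stage symptom probabilities.
#'
#' @param symptom_prob named numeric, per-stage annual symptom probabilities
#'   (stages I-IV).
#' @param params a `bc_parameters` object (its `symptom_prob` is replaced).
#' @param life_table a `bc_life_table` covering the horizon.
#' @return numeric vector of proportions over stages I-IV, summing to 1.
#' @export
presentation_distribution <- function(symptom_prob, params, life_table) {
  if (all(symptom_prob == 0)) {
    stop("degenerate-distribution error: all symptom probabilities are zero",
         call. = FALSE)
  }
  params$symptom_prob <- stats::setNames(as.numeric(symptom_prob), STAGES)
  res <- run_cohort(no_screening(), params, life_table)
  by_stage <- res$symptom_detected_by_stage
  total <- sum(by_stage)
  if (total <= 0) {
    stop("degenerate-distribution error: no symptomatic presentations occurred",
         call. = FALSE)
  }
  stats::setNames(as.numeric(by_stage / total), STAGES)
}

logit <- function(p) log(p / (1 - p))
expit <- function(x) 1 / (1 + exp(-x))

#' Calibrate stage-specific symptom probabilities
#'
#' Adjusts the four per-stage annual symptom probabilities until the
#' unscreened model's stage distribution at presentation matches a target
#' distribution (e.g. a cancer registry's reported stage distribution of
#' incident cases). The search is a derivative-free Nelder-Mead simplex on the
#' logit scale, minimising the L2 distance between model and target
#' distributions, with a fixed start so the result is deterministic.
#'
#' @param target numeric length-4 target proportions over stages I-IV
#'   (non-negative, summing to 1).
#' @param params a `bc_parameters` object.
#' @param life_table a `bc_life_table`.
#' @param init starting symptom probabilities.
#' @param tol convergence tolerance on the L2 residual.
#' @param max_iter maximum objective evaluations.
#' @return named numeric of calibrated probabilities (stages I-IV), with the
#'   achieved residual in attribute `"residual"`.
#' @export
calibrate_symptom_probs <- function(target, params, life_table,
                                    init = c(I = 0.01, II = 0.05,
                                             III = 0.3, IV = 0.9),
                                    tol = 1e-4, max_iter = 2000) {
  if (length(target) != 4 || any(target < 0)) {
    stop("validation error: target must be 4 non-negative proportions",
         call. = FALSE)
  }
  if (abs(sum(target) - 1) > 1e-9) {
    stop("validation error: target proportions must sum to 1", call. = FALSE)
  }
  if (tol <= 0) stop("validation error: tol must be > 0", call. = FALSE)
  obj <- function(x) {
    p <- expit(x)
    sqrt(sum((presentation_distribution(p, params, life_table) - target)^2))
  }
  fit <- stats::optim(logit(pmin(pmax(init, 1e-6), 1 - 1e-6)), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = max_iter, reltol = 1e-12))
  # polish: restart once from the optimum (standard Nelder-Mead practice)
  fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                      control = list(maxit = max_iter, reltol = 1e-12))
  if (fit$value > tol) {
    stop(sprintf(
      "convergence error: best L2 residual %.3g exceeds tol %.3g after %d evaluations",
      fit$value, tol, max_iter), call. = FALSE)
  }
  out <- stats::setNames(expit(fit$par), STAGES)
  attr(out, "residual") <- fit$value
  out
}
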