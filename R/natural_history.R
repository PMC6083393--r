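# Health-state layout of the cohort occupancy vector. Undiagnosed disease
# (DCIS and preclinical stages I-IV) is asymptomatic and unknown to the woman;
# diagnosed disease is split by whether treatment was taken up.
S_HEALTHY <- 1L
S_DCIS    <- 2L
S_PRE     <- 3:6    # preclinical stages I..IV
S_TDCIS   <- 7L     # treated DCIS
S_TREAT   <- 8:11   # treated stages I..IV
S_DIAG    <- 12:15  # diagnosed-untreated stages I..IV
S_BCDEATH <- 16L
S_OCDEATH <- 17L
N_STATES  <- 17L

#' Health-state names of the cohort model
#'
#' Order matches the rows/columns of [build_transition_matrix()] and the
#' occupancy trace of [run_cohort()].
#' @return character vector of the 17 state names.
#' @export
health_states <- function() {
  c("Healthy", "DCIS",
    paste0("PreclinicalStage", STAGES),
    "TreatedDCIS", paste0("TreatedStage", STAGES),
    paste0("DiagnosedUntreatedStage", STAGES),
    "BreastCancerDeath", "OtherDeath")
}

# -- one-year event steps ------------------------------------------------------
# Within a cycle events fire in a fixed order, each conditioned on the earlier
# ones not having fired: (1) other-cause death, (2) breast-cancer death,
# (3) scheduled screening, (4) symptomatic presentation, (5) onset/progression.
# Sequential conditioning keeps every implied transition row stochastic without
# renormalisation.

step_deaths <- function(pi, q_oc, params) {
  living <- c(S_HEALTHY, S_DCIS, S_PRE, S_TDCIS, S_TREAT, S_DIAG)
  dying <- pi[living] * q_oc
  pi[living] <- pi[living] - dying
  pi[S_OCDEATH] <- pi[S_OCDEATH] + sum(dying)
  # breast-cancer death, conditional on surviving other causes
  fatal_idx <- c(S_PRE[4], S_DIAG[4], S_TREAT)
  fatal_p <- c(params$progression[["IV_death"]], params$progression[["IV_death"]],
               params$fatality_treated[STAGES])
  bc <- pi[fatal_idx] * fatal_p
  pi[fatal_idx] <- pi[fatal_idx] - bc
  pi[S_BCDEATH] <- pi[S_BCDEATH] + sum(bc)
  pi
}

step_symptoms <- function(pi, params, uptake) {
  presenting <- pi[S_PRE] * params$symptom_prob[STAGES]
  pi[S_PRE] <- pi[S_PRE] - presenting
  pi[S_TREAT] <- pi[S_TREAT] + presenting * uptake
  pi[S_DIAG] <- pi[S_DIAG] + presenting * (1 - uptake)
  list(pi = pi, presented = unname(presenting))
}

step_onset_progression <- function(pi, age, params) {
  p_inv <- onset_probability(age, params, "invasive")
  p_dcis_cond <- params$dcis_ratio * p_inv  # DCIS onset, given no invasive onset
  # healthy: invasive onset first, then DCIS among those without invasive onset
  inv_from_healthy <- pi[S_HEALTHY] * p_inv
  dcis_new <- (pi[S_HEALTHY] - inv_from_healthy) * p_dcis_cond
  inv_from_dcis <- pi[S_DCIS] * min(1, params$rr_dcis_to_invasive * p_inv)
  # stage progression, simultaneous update from the pre-step occupancy
  prog <- c(params$progression[["I_II"]], params$progression[["II_III"]],
            params$progression[["III_IV"]])
  pre_moves <- pi[S_PRE[1:3]] * prog
  diag_moves <- pi[S_DIAG[1:3]] * prog
  pi[S_HEALTHY] <- pi[S_HEALTHY] - inv_from_healthy - dcis_new
  pi[S_DCIS] <- pi[S_DCIS] + dcis_new - inv_from_dcis
  pi[S_PRE[1]] <- pi[S_PRE[1]] + inv_from_healthy + inv_from_dcis - pre_moves[1]
  pi[S_PRE[2]] <- pi[S_PRE[2]] + pre_moves[1] - pre_moves[2]
  pi[S_PRE[3]] <- pi[S_PRE[3]] + pre_moves[2] - pre_moves[3]
  pi[S_PRE[4]] <- pi[S_PRE[4]] + pre_moves[3]
  pi[S_DIAG[1]] <- pi[S_DIAG[1]] - diag_moves[1]
  pi[S_DIAG[2]] <- pi[S_DIAG[2]] + diag_moves[1] - diag_moves[2]
  pi[S_DIAG[3]] <- pi[S_DIAG[3]] + diag_moves[2] - diag_moves[3]
  pi[S_DIAG[4]] <- pi[S_DIAG[4]] + diag_moves[3]
  list(pi = pi, invasive_onsets = inv_from_healthy + inv_from_dcis)
}

# one unscreened model year: deaths, symptomatic presentation, onset/progression
natural_history_year <- function(pi, age, params, life_table, uptake) {
  pi <- step_deaths(pi, lt_qx(life_table, age), params)
  pi <- step_symptoms(pi, params, uptake)$pi
  step_onset_progression(pi, age, params)$pi
}

#' Annual transition matrix of the unscreened natural-history process
#'
#' Assembles the one-year transition probabilities between all health states
#' at a given age: onset of DCIS and invasive disease from the healthy state,
#' DCIS-to-invasive transition (at `rr_dcis_to_invasive` times the invasive
#' onset probability), stage-to-stage progression, symptomatic presentation
#' into the diagnosed states, breast-cancer death from stage IV (untreated) and
#' from treated states via the post-treatment fatality rates, and other-cause
#' death from every living state at the life-table rate. Competing events are
#' resolved sequentially-conditionally in the fixed cycle order, so each row is
#' exactly stochastic.
#'
#' @param age age in completed years.
#' @param params a `bc_parameters` object.
#' @param strategy a `bc_strategy`; only `treatment_uptake` enters (the matrix
#'   describes an unscreened year — screening rounds are applied separately by
#'   [apply_screening_round()]).
#' @param life_table a `bc_life_table` covering `age`.
#' @return a 17 x 17 row-stochastic matrix with dimnames [health_states()].
#' @export
build_transition_matrix <- function(age, params, strategy = no_screening(),
                                    life_table) {
  M <- matrix(0, N_STATES, N_STATES,
              dimnames = list(health_states(), health_states()))
  for (s in seq_len(N_STATES)) {
    e <- numeric(N_STATES); e[s] <- 1
    M[s, ] <- natural_history_year(e, age, params, life_table,
                                   strategy$treatment_uptake)
  }
  M
}
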