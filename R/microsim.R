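# Individual-level Monte-Carlo re-implementation of the screening model,
# used as an independent oracle for the deterministic cohort recursion. It
# shares the parameter and strategy objects and the fixed within-cycle event
# order, but samples each woman's history directly (no transition matrices),
# so agreement between the two engines is evidence rather than tautology.

#' Individual-level microsimulation of the screening model
#'
#' Simulates `n_women` independent life histories from age 40 under the same
#' event-order convention as [run_cohort()] (other-cause death, breast-cancer
#' death, screening, symptomatic presentation, onset/progression, then one
#' year of utility accrual), accumulating per-woman discounted costs and
#' QALYs. As `n_women` grows the means converge to the cohort recursion's
#' outputs; the returned standard errors quantify the Monte-Carlo noise.
#'
#' @param n_women number of women to simulate.
#' @param seed RNG seed; the same seed reproduces the run exactly.
#' @param strategy a `bc_strategy`.
#' @param params a `bc_parameters` object.
#' @param life_table a `bc_life_table` covering the horizon.
#' @return list with `mean_cost`, `mean_qaly`, `se_cost`, `se_qaly`, their
#'   undiscounted twins, `counts_per_1000` (incident, screen-detected,
#'   symptom-detected) and `n`.
#' @export
simulate_cohort <- function(n_women, seed, strategy, params, life_table) {
  stopifnot(n_women >= 1)
  set.seed(seed)
  n <- as.integer(n_women)
  ages <- 40:params$age_max
  r <- params$discount_rate
  uptake <- strategy$treatment_uptake
  prog <- params$progression
  symp <- params$symptom_prob[STAGES]
  fatal <- params$fatality_treated[STAGES]
  treat_cost <- vapply(c("DCIS", STAGES),
                       function(s) params$costs$treatment[[s]][["baseline"]],
                       numeric(1))
  c_quest <- params$costs$questionnaire[["baseline"]]
  c_screen <- params$costs$screening[["baseline"]]
  c_biopsy <- params$costs$biopsy[["baseline"]]
  disut <- params$disutility_fp[["baseline"]] * params$fp_duration_years
  u_state <- state_utilities(params)

  state <- rep(S_HEALTHY, n)
  cost <- qaly <- ucost <- uqaly <- numeric(n)
  ever_incident <- ever_screen_det <- ever_symptom_det <- logical(n)

  for (k in seq_along(ages)) {
    age <- ages[k]
    d <- discount_factor(k - 1L, r)
    alive <- state <= S_DIAG[4]
    if (!any(alive)) break

    # (1) other-cause death
    idx <- which(alive)
    dies <- idx[stats::runif(length(idx)) < lt_qx(life_table, age)]
    state[dies] <- S_OCDEATH
    # (2) breast-cancer death
    for (sidx in list(c(S_PRE[4], prog[["IV_death"]]),
                      c(S_DIAG[4], prog[["IV_death"]]))) {
      idx <- which(state == sidx[1])
      if (length(idx)) {
        state[idx[stats::runif(length(idx)) < sidx[2]]] <- S_BCDEATH
      }
    }
    for (s in 1:4) {
      idx <- which(state == S_TREAT[s])
      if (length(idx)) {
        state[idx[stats::runif(length(idx)) < fatal[s]]] <- S_BCDEATH
      }
    }

    # (3) screening
    fp <- logical(n)
    if (screening_due(age, strategy)) {
      tc <- test_characteristics(age, strategy, params)
      attend <- which(state >= S_HEALTHY & state <= S_PRE[4])
      cost[attend] <- cost[attend] + d * (c_quest + c_screen)
      ucost[attend] <- ucost[attend] + (c_quest + c_screen)
      healthy <- attend[state[attend] == S_HEALTHY]
      pos <- healthy[stats::runif(length(healthy)) > tc$specificity]
      fp[pos] <- TRUE
      cost[pos] <- cost[pos] + d * c_biopsy
      ucost[pos] <- ucost[pos] + c_biopsy
      # DCIS detection
      idx <- which(state == S_DCIS)
      det <- idx[stats::runif(length(idx)) < tc$sensitivity]
      if (length(det)) {
        cost[det] <- cost[det] + d * c_biopsy
        ucost[det] <- ucost[det] + c_biopsy
        treated <- det[stats::runif(length(det)) < uptake]
        state[treated] <- S_TDCIS
        cost[treated] <- cost[treated] + d * treat_cost[["DCIS"]]
        ucost[treated] <- ucost[treated] + treat_cost[["DCIS"]]
        ever_screen_det[treated] <- TRUE
        ever_incident[treated] <- TRUE  # DCIS counts as incident when detected
      }
      for (s in 1:4) {
        idx <- which(state == S_PRE[s])
        det <- idx[stats::runif(length(idx)) < tc$sensitivity]
        if (length(det)) {
          cost[det] <- cost[det] + d * c_biopsy
          ucost[det] <- ucost[det] + c_biopsy
          take <- stats::runif(length(det)) < uptake
          state[det[take]] <- S_TREAT[s]
          state[det[!take]] <- S_DIAG[s]
          cost[det[take]] <- cost[det[take]] + d * treat_cost[[STAGES[s]]]
          ucost[det[take]] <- ucost[det[take]] + treat_cost[[STAGES[s]]]
          ever_screen_det[det] <- TRUE
        }
      }
    }

    # (4) symptomatic presentation
    for (s in 1:4) {
      idx <- which(state == S_PRE[s])
      pres <- idx[stats::runif(length(idx)) < symp[s]]
      if (length(pres)) {
        take <- stats::runif(length(pres)) < uptake
        state[pres[take]] <- S_TREAT[s]
        state[pres[!take]] <- S_DIAG[s]
        cost[pres[take]] <- cost[pres[take]] + d * treat_cost[[STAGES[s]]]
        ucost[pres[take]] <- ucost[pres[take]] + treat_cost[[STAGES[s]]]
        ever_symptom_det[pres] <- TRUE
      }
    }

    # (5) onset and progression; progression processed from late stages down
    # so one woman moves at most one stage per cycle
    p_inv <- onset_probability(age, params, "invasive")
    p_dcis_cond <- params$dcis_ratio * p_inv
    p_from_dcis <- min(1, params$rr_dcis_to_invasive * p_inv)
    for (s in 3:1) {
      pr <- prog[[c("I_II", "II_III", "III_IV")[s]]]
      idx <- which(state == S_PRE[s])
      state[idx[stats::runif(length(idx)) < pr]] <- S_PRE[s + 1]
      idx <- which(state == S_DIAG[s])
      state[idx[stats::runif(length(idx)) < pr]] <- S_DIAG[s + 1]
    }
    idx <- which(state == S_DCIS)
    onset <- idx[stats::runif(length(idx)) < p_from_dcis]
    state[onset] <- S_PRE[1]
    ever_incident[onset] <- TRUE
    idx <- which(state == S_HEALTHY)
    u1 <- stats::runif(length(idx))
    onset <- idx[u1 < p_inv]
    state[onset] <- S_PRE[1]
    ever_incident[onset] <- TRUE
    rest <- idx[u1 >= p_inv]
    state[rest[stats::runif(length(rest)) < p_dcis_cond]] <- S_DCIS

    # utility accrual for the year
    uy <- u_state[state]
    uy[fp] <- uy[fp] - disut
    qaly <- qaly + d * uy
    uqaly <- uqaly + uy
  }

  list(
    mean_cost = mean(cost), mean_qaly = mean(qaly),
    se_cost = stats::sd(cost) / sqrt(n), se_qaly = stats::sd(qaly) / sqrt(n),
    mean_undiscounted_cost = mean(ucost),
    mean_undiscounted_qaly = mean(uqaly),
    counts_per_1000 = c(
      incident = 1000 * mean(ever_incident),
      screen_detected = 1000 * mean(ever_screen_det),
      symptom_detected = 1000 * mean(ever_symptom_det)),
    n = n, seed = seed
  )
}

#' Synthetic Gompertz life table
#'
#' Generates an other-cause mortality schedule from a Gompertz hazard
#' `h(a) = level * exp(slope * (a - 40))`, converted to annual death
#' probabilities by integrating the hazard over each year of age. The defaults
#' (`level = 9e-4`, `slope = 0.10`) emulate adult female mortality in urban
#' China — remaining life expectancy at 40 of about 41 years, with adult
#' mortality doubling roughly every 7 years — and stand in for a national
#' female life table in tests and examples; real schedules wobble around a
#' Gompertz curve and should be supplied via [bc_life_table()] when available.
#'
#' @param level hazard at age 40 (per year), > 0.
#' @param slope log-hazard increase per year of age, >= 0.
#' @param age_range two integers, ages covered (inclusive).
#' @return a `bc_life_table`.
#' @export
synthetic_life_table <- function(level = 9e-4, slope = 0.10,
                                 age_range = c(40L, 100L)) {
  if (level <= 0) stop("validation error: level must be > 0", call. = FALSE)
  if (slope < 0) stop("validation error: slope must be >= 0", call. = FALSE)
  ages <- age_range[1]:age_range[2]
  H <- if (slope == 0) {
    rep(level, length(ages))
  } else {
    (level / slope) * (exp(slope * (ages + 1 - 40)) - exp(slope * (ages - 40)))
  }
  qx <- 1 - exp(-H)
  if (any(qx >= 1)) {
    stop("validation error: parameters produce death probability >= 1 before age_max",
         call. = FALSE)
  }
  bc_life_table(ages, qx)
}

#' Random valid parameter set for property testing
#'
#' Draws every baseline value within +/-50% of its default, truncated to its
#' valid range, and rebuilds consistent min/max bounds around the drawn
#' baseline, so the result always passes [bc_parameters()] validation.
#'
#' @param seed RNG seed.
#' @return a `bc_parameters` object.
#' @export
random_parameter_set <- function(seed) {
  set.seed(seed)
  jit <- function(x, cap = Inf, floor = 1e-6) {
    pmin(pmax(x * stats::runif(length(x), 0.5, 1.5), floor), cap)
  }
  jit_triple <- function(tr, cap = Inf) {
    b <- jit(tr[["baseline"]], cap = cap)
    c(baseline = b, min = max(b * 0.8, 1e-6), max = min(b * 1.2, cap))
  }
  base <- bc_parameters()
  bc_parameters(
    incidence_by_age = jit(base$incidence_by_age, cap = 0.05),
    dcis_ratio = jit(base$dcis_ratio, cap = 1),
    rr_dcis_to_invasive = jit(base$rr_dcis_to_invasive),
    rr_high_risk = jit(base$rr_high_risk),
    progression = jit(base$progression, cap = 0.95),
    symptom_prob = jit(base$symptom_prob, cap = 0.995),
    fatality_treated = jit(base$fatality_treated, cap = 0.95),
    test_perf = lapply(base$test_perf, function(tp) {
      list(sensitivity = jit_triple(tp$sensitivity, cap = 0.999),
           specificity = jit_triple(tp$specificity, cap = 0.999))
    }),
    utility = lapply(base$utility, jit_triple, cap = 1),
    disutility_fp = jit_triple(base$disutility_fp, cap = 1),
    costs = list(
      questionnaire = jit_triple(base$costs$questionnaire),
      screening = jit_triple(base$costs$screening),
      biopsy = jit_triple(base$costs$biopsy),
      treatment = lapply(base$costs$treatment, jit_triple)),
    discount_rate = base$discount_rate,
    wtp_threshold = base$wtp_threshold
  )
}
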