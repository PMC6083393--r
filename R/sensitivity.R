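# Parameter paths address the baseline of any quantity carrying an
# uncertainty range, e.g. "costs.treatment.I" or
# "test_perf.us_plus_mammo.sensitivity". These are exactly the quantities
# varied in one-way and probabilistic sensitivity analyses; probabilities
# without ranges (incidence, progression, symptoms, fatality) stay fixed.

ranged_paths <- function(params) {
  sort(c(
    paste0("test_perf.", rep(names(params$test_perf), each = 2),
           c(".sensitivity", ".specificity")),
    paste0("utility.", STAGES),
    "disutility_fp",
    paste0("costs.", c("questionnaire", "screening", "biopsy")),
    paste0("costs.treatment.", c("DCIS", STAGES))
  ))
}

get_triple <- function(params, path) {
  node <- unclass(params)
  for (key in strsplit(path, ".", fixed = TRUE)[[1]]) {
    node <- node[[key]]
    if (is.null(node)) {
      stop("unsupported-parameter error: no parameter at path '", path, "'",
           call. = FALSE)
    }
  }
  node
}

set_baseline <- function(params, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  rec <- function(node, keys) {
    if (!length(keys)) {
      node[["baseline"]] <- value
      return(node)
    }
    if (is.null(node[[keys[1]]])) {
      stop("unsupported-parameter error: no parameter at path '", path, "'",
           call. = FALSE)
    }
    node[[keys[1]]] <- rec(node[[keys[1]]], keys[-1])
    node
  }
  out <- rec(unclass(params), keys)
  class(out) <- "bc_parameters"
  out
}

path_family <- function(path) {
  if (startsWith(path, "costs")) "gamma"
  else if (startsWith(path, "test_perf")) "beta"
  else "log-normal"  # utilities and disutility
}

#' Fit a sampling distribution to a baseline and range
#'
#' Builds the distribution used for a parameter in probabilistic sensitivity
#' analysis: the mean is pinned at the baseline and the spread is derived by
#' reading `(min, max)` as an approximate central 95% interval
#' (`sd = (max - min) / 3.92`), with family parameters then obtained by moment
#' matching. A degenerate range (`min = baseline = max`) yields a point mass.
#'
#' @param baseline,min,max the parameter triple.
#' @param family `"gamma"` (costs), `"log-normal"` (utilities), or `"beta"`
#'   (test sensitivity/specificity).
#' @return a distribution spec: list with `family`, `mean`, `sd` and the
#'   family parameters.
#' @export
fit_distribution <- function(baseline, min, max,
                             family = c("gamma", "log-normal", "beta")) {
  family <- match.arg(family)
  if (is.na(min) || is.na(max)) {
    stop("unsupported-parameter error: no range available for fitting",
         call. = FALSE)
  }
  if (min > baseline || baseline > max) {
    stop("validation error: need min <= baseline <= max", call. = FALSE)
  }
  if (min == max) {
    return(list(family = "point", mean = baseline, sd = 0))
  }
  m <- baseline
  s <- (max - min) / (2 * stats::qnorm(0.975))
  v <- s^2
  out <- switch(family,
    "gamma" = {
      if (m <= 0) stop("fit error: gamma requires a positive mean", call. = FALSE)
      list(family = "gamma", mean = m, sd = s, shape = m^2 / v, rate = m / v)
    },
    "log-normal" = {
      if (m <= 0) stop("fit error: log-normal requires a positive mean",
                       call. = FALSE)
      sdlog2 <- log(1 + v / m^2)
      list(family = "log-normal", mean = m, sd = s,
           meanlog = log(m) - sdlog2 / 2, sdlog = sqrt(sdlog2))
    },
    "beta" = {
      if (m <= 0 || m >= 1) stop("fit error: beta requires mean in (0, 1)",
                                 call. = FALSE)
      if (v >= m * (1 - m)) {
        stop(sprintf(
          "fit error: variance %.4g infeasible for beta with mean %.4g (achievable quantiles narrower than [%.4g, %.4g])",
          v, m, min, max), call. = FALSE)
      }
      k <- m * (1 - m) / v - 1
      list(family = "beta", mean = m, sd = s, shape1 = m * k,
           shape2 = (1 - m) * k)
    })
  out
}

#' Draw samples from a fitted distribution spec
#' @param spec a spec from [fit_distribution()].
#' @param n number of draws.
#' @return numeric vector; utilities/probabilities are capped at 1.
#' @export
draw_from_spec <- function(spec, n) {
  x <- switch(spec$family,
    "point" = rep(spec$mean, n),
    "gamma" = stats::rgamma(n, shape = spec$shape, rate = spec$rate),
    "log-normal" = stats::rlnorm(n, meanlog = spec$meanlog, sdlog = spec$sdlog),
    "beta" = stats::rbeta(n, shape1 = spec$shape1, shape2 = spec$shape2),
    stop("unknown distribution family: ", spec$family, call. = FALSE))
  x
}

icer_at <- function(params, path, value, strategy, comparator, life_table) {
  p2 <- set_baseline(params, path, value)
  cmp <- compare_strategies(run_cohort(strategy, p2, life_table),
                            run_cohort(comparator, p2, life_table),
                            p2$wtp_threshold)
  cmp$icer
}

#' One-way sensitivity analysis for a single parameter
#'
#' Re-evaluates both model arms with the parameter set to its lower and upper
#' bound (all other parameters at baseline) and reports the two ICERs.
#'
#' @param param_path dot-separated path, e.g. `"costs.treatment.I"`.
#' @param strategy,comparator `bc_strategy` objects.
#' @param params a `bc_parameters` object.
#' @param life_table a `bc_life_table`.
#' @param lo,hi bounds; default to the parameter's min/max range.
#' @return list with `icer_at_lo`, `icer_at_hi`, `lo`, `hi`, `param_path`.
#' @export
one_way <- function(param_path, strategy, comparator, params, life_table,
                    lo = NULL, hi = NULL) {
  tr <- get_triple(params, param_path)
  if (!all(c("baseline", "min", "max") %in% names(tr))) {
    stop("unsupported-parameter error: '", param_path,
         "' is not a baseline/min/max quantity", call. = FALSE)
  }
  if (is.null(lo)) lo <- unname(tr[["min"]])
  if (is.null(hi)) hi <- unname(tr[["max"]])
  if (is.na(lo) || is.na(hi)) {
    stop("unsupported-parameter error: '", param_path,
         "' carries no uncertainty range", call. = FALSE)
  }
  list(param_path = param_path, lo = lo, hi = hi,
       icer_at_lo = icer_at(params, param_path, lo, strategy, comparator,
                            life_table),
       icer_at_hi = icer_at(params, param_path, hi, strategy, comparator,
                            life_table))
}

#' Tornado table over every ranged parameter
#'
#' Runs [one_way()] for each parameter carrying a min/max range and returns a
#' table sorted by decreasing ICER span — the data behind a tornado diagram.
#'
#' @inheritParams one_way
#' @return data.frame with one row per parameter: bounds, the two ICERs, and
#'   the absolute span.
#' @export
tornado <- function(strategy, comparator, params, life_table) {
  rows <- lapply(ranged_paths(params), function(path) {
    ow <- one_way(path, strategy, comparator, params, life_table)
    data.frame(param = path, lo = ow$lo, hi = ow$hi,
               icer_at_lo = ow$icer_at_lo, icer_at_hi = ow$icer_at_hi,
               span = abs(ow$icer_at_hi - ow$icer_at_lo),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$span), , drop = FALSE]
}

#' Probabilistic sensitivity analysis
#'
#' Draws every ranged parameter from its fitted distribution (gamma for costs,
#' log-normal for utilities and the false-positive disutility, beta for test
#' sensitivity and specificity), re-runs both model arms per draw, and returns
#' the paired incremental cost and QALY samples. Draw order is fixed by sorted
#' parameter path, so a given seed reproduces the draws exactly.
#'
#' @param n number of draws.
#' @param seed RNG seed.
#' @param strategy,comparator `bc_strategy` objects.
#' @param params a `bc_parameters` object.
#' @param life_table a `bc_life_table`.
#' @return an object of class `bc_psa_draws`: `draws` (data.frame with
#'   `incremental_cost`, `incremental_qaly`), `seed`, `specs` (per-parameter
#'   distribution specs), `wtp_threshold`.
#' @export
run_psa <- function(n, seed, strategy, comparator, params, life_table) {
  stopifnot(n >= 1)
  set.seed(seed)
  paths <- ranged_paths(params)
  specs <- lapply(stats::setNames(paths, paths), function(path) {
    tr <- get_triple(params, path)
    fit_distribution(tr[["baseline"]], tr[["min"]], tr[["max"]],
                     path_family(path))
  })
  samples <- vapply(paths, function(path) {
    x <- draw_from_spec(specs[[path]], n)
    # utilities, disutility and test performance live in [0, 1]
    if (path_family(path) != "gamma") x <- pmin(x, 1)
    x
  }, numeric(n))
  samples <- matrix(samples, nrow = n, dimnames = list(NULL, paths))
  dC <- dE <- numeric(n)
  for (i in seq_len(n)) {
    p_i <- params
    for (path in paths) p_i <- set_baseline(p_i, path, samples[i, path])
    res_i <- run_cohort(strategy, p_i, life_table)
    res_c <- run_cohort(comparator, p_i, life_table)
    dC[i] <- res_i$discounted_cost - res_c$discounted_cost
    dE[i] <- res_i$discounted_qaly - res_c$discounted_qaly
  }
  structure(list(
    draws = data.frame(incremental_cost = dC, incremental_qaly = dE),
    samples = samples, specs = specs, seed = seed, n = n,
    wtp_threshold = params$wtp_threshold
  ), class = "bc_psa_draws")
}

#' @export
print.bc_psa_draws <- function(x, ...) {
  cat("<bc_psa_draws>", x$n, "draws, seed", x$seed, "\n")
  cat(sprintf("  mean dCost US$ %.2f | mean dQALY %.4f | P(CE at %g) = %.3f\n",
              mean(x$draws$incremental_cost), mean(x$draws$incremental_qaly),
              x$wtp_threshold,
              mean(x$wtp_threshold * x$draws$incremental_qaly -
                     x$draws$incremental_cost > 0)))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA draws with positive
#' net monetary benefit.
#'
#' @param draws a `bc_psa_draws`.
#' @param wtp_grid numeric vector of willingness-to-pay values.
#' @return data.frame with `wtp` and `p_cost_effective`.
#' @export
ceac <- function(draws, wtp_grid) {
  if (!length(wtp_grid)) stop("domain error: empty WTP grid", call. = FALSE)
  p <- vapply(wtp_grid, function(w) {
    mean(w * draws$draws$incremental_qaly - draws$draws$incremental_cost > 0)
  }, numeric(1))
  data.frame(wtp = wtp_grid, p_cost_effective = p)
}

#' Scenario grid: screening intervals, treatment uptake, modality choice
#'
#' Evaluates annual, 3-yearly and 5-yearly screening against no screening,
#' plus annual screening with 70% treatment uptake. When the parameter set
#' supplies a `mammo_alone` modality (its test performance is not part of the
#' bundled defaults and must come from the user's configuration), the
#' combined ultrasound-plus-mammography strategy for ages 45-69 is additionally
#' compared against mammography alone at each interval; otherwise that block
#' is skipped with a warning.
#'
#' When `params$high_risk_comparator` is `FALSE` the no-screening comparator
#' is evaluated at general-population risk (`rr_high_risk = 1`).
#'
#' @param params a `bc_parameters` object.
#' @param life_table a `bc_life_table`.
#' @return data.frame in report layout (one row per comparison).
#' @export
run_scenarios <- function(params, life_table) {
  comp_params <- params
  if (!params$high_risk_comparator) comp_params$rr_high_risk <- 1
  res_none <- run_cohort(no_screening(), comp_params, life_table)
  strategies <- list(
    bc_strategy("annual", 1),
    bc_strategy("every_3_years", 3),
    bc_strategy("every_5_years", 5),
    bc_strategy("annual_70pct_treated", 1, treatment_uptake = 0.7)
  )
  rows <- ce_table(c(list(res_none),
                     lapply(strategies, run_cohort, params = params,
                            life_table = life_table)),
                   params$wtp_threshold)
  if (is.null(params$test_perf$mammo_alone)) {
    warning("mammography-alone test performance not supplied; ",
            "modality comparison scenarios skipped", call. = FALSE)
    return(rows)
  }
  for (iv in c(1L, 3L, 5L)) {
    combined <- bc_strategy(paste0("us_plus_mammo_q", iv), iv)
    mammo <- bc_strategy(paste0("mammo_alone_q", iv), iv,
                         modality_by_age_band = list(
                           "40-44" = "us_then_mammo",
                           "45-69" = "mammo_alone"))
    res_m <- run_cohort(mammo, params, life_table)
    res_c <- run_cohort(combined, params, life_table)
    cmp <- compare_strategies(res_c, res_m, params$wtp_threshold)
    rows <- rbind(rows, data.frame(
      strategy = paste0(combined$name, "_vs_mammo_alone"),
      cost = res_c$discounted_cost, qaly = res_c$discounted_qaly,
      incremental_cost = cmp$incremental_cost,
      incremental_qaly = cmp$incremental_qaly,
      icer = cmp$icer, stringsAsFactors = FALSE))
  }
  rows
}
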