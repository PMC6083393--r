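# Shared fixtures: baseline parameters, the synthetic life table, and cached
# cohort runs reused across test files.

base_params <- bc_parameters()
base_lt <- synthetic_life_table()

# a life table with no other-cause mortality, for isolating disease dynamics
zero_lt <- bc_life_table(40:100, rep(0, 61))

# closed-form discounted life expectancy oracle: survival products from the
# life table, deaths at the start of each cycle, survivors accrue one year
discounted_le <- function(lt, rate) {
  ages <- as.integer(names(lt))
  S <- cumprod(1 - unname(lt))
  sum(S / (1 + rate)^(seq_along(ages) - 1))
}

cohort_cache <- new.env(parent = emptyenv())
cached_run <- function(key, strategy, params = base_params, lt = base_lt) {
  if (is.null(cohort_cache[[key]])) {
    cohort_cache[[key]] <- run_cohort(strategy, params, lt)
  }
  cohort_cache[[key]]
}
res_none <- function() cached_run("none", no_screening())
res_annual <- function() cached_run("annual", bc_strategy("annual", 1))
res_q3 <- function() cached_run("q3", bc_strategy("every_3_years", 3))
res_q5 <- function() cached_run("q5", bc_strategy("every_5_years", 5))
res_a70 <- function() {
  cached_run("a70", bc_strategy("annual_70pct", 1, treatment_uptake = 0.7))
}
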