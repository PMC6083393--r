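test_that("baseline defaults carry the programme's parameter values", {
  p <- base_params
  expect_equal(unname(p$progression[c("I_II", "II_III", "III_IV", "IV_death")]),
               c(0.06, 0.11, 0.15, 0.23))
  expect_equal(vapply(c("I", "II", "III", "IV"),
                      function(s) p$utility[[s]][["baseline"]], numeric(1)),
               c(I = 0.79, II = 0.79, III = 0.77, IV = 0.69))
  expect_equal(unname(p$symptom_prob), c(0.004, 0.014, 0.380, 0.980))
  expect_equal(p$test_perf$us_then_mammo$sensitivity[["baseline"]], 0.848)
  expect_equal(p$test_perf$us_plus_mammo$specificity[["baseline"]], 0.980)
  expect_equal(p$costs$treatment$I[["baseline"]], 10067)
  expect_equal(p$discount_rate, 0.03)
  expect_equal(p$wtp_threshold, 23050)
})

test_that("out-of-range and incomplete configurations are rejected", {
  expect_error(load_parameters(list(utility = list(I = list(baseline = 1.3)))),
               "utility.I")
  expect_error(bc_parameters(discount_rate = -0.01), "discount_rate")
  expect_error(bc_parameters(rr_high_risk = 0), "rr_high_risk")
  expect_error(bc_parameters(incidence_by_age = DEFAULT_INCIDENCE[-3]),
               "50-54")
  expect_error(bc_parameters(progression = c(I_II = 0.06)), "progression")
  expect_error(
    load_parameters(list(costs = list(biopsy = list(baseline = -5)))),
    "costs.biopsy")
})

test_that("onset probability scales band incidence by relative risk", {
  p <- base_params
  expect_equal(onset_probability(47, p, "invasive"), 2 * 0.0010056)
  expect_equal(onset_probability(47, p, "dcis"), 0.12 * 2 * 0.0010056)
  p1 <- bc_parameters(rr_high_risk = 1)
  expect_equal(onset_probability(47, p1, "invasive"), 0.0010056)
  expect_error(onset_probability(39, p), "domain error")
  expect_error(onset_probability(101, p), "domain error")
  # linear in relative risk, bounded by 1, for every age in the horizon
  for (rr in c(0.5, 3, 10)) {
    prr <- bc_parameters(rr_high_risk = rr)
    ages <- 40:100
    expect_equal(onset_probability(ages, prr, "invasive"),
                 pmin(1, rr * onset_probability(ages, p1, "invasive")))
    expect_true(all(onset_probability(ages, prr, "invasive") <= 1))
  }
})

test_that("ages at and above 85 use the open upper incidence band", {
  p <- base_params
  expect_equal(onset_probability(85, p, "invasive"), 2 * 0.0006430)
  expect_equal(onset_probability(97, p, "invasive"), 2 * 0.0006430)
})

test_that("configuration serialization round-trips", {
  p <- bc_parameters(rr_high_risk = 1.7, discount_rate = 0.05)
  f <- withr::local_tempfile(fileext = ".yaml")
  serialize_parameters(p, f)
  expect_equal(unclass(load_parameters(f)), unclass(p), tolerance = 1e-12)
  # bundled configuration reproduces the defaults exactly
  bundled <- system.file("extdata", "params_table1.yaml", package = "bcscreen")
  expect_equal(unclass(load_parameters(bundled)), unclass(base_params),
               tolerance = 1e-12)
})

test_that("strategy definitions are validated", {
  expect_error(bc_strategy(treatment_uptake = 1.2), "treatment_uptake")
  expect_error(bc_strategy(interval_years = -1), "interval_years")
  expect_error(bc_strategy(modality_by_age_band = list("40-50" = "us_then_mammo")),
               "tile")
  s <- no_screening()
  expect_identical(s$interval_years, 0L)
  expect_s3_class(bc_strategy("q3", 3), "bc_strategy")
})

test_that("life tables demand matching lengths and valid probabilities", {
  expect_error(bc_life_table(40:41, 0.1), "equal length")
  expect_error(bc_life_table(40:41, c(0.1, 1.2)), "\\[0, 1\\]")
  lt <- bc_life_table(40:42, c(0.01, 0.02, 0.03))
  expect_equal(unname(lt[["41"]]), 0.02)
})
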