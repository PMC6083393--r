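test_that("fitted distributions pin the mean at baseline with a 95%-range spread", {
  b <- fit_distribution(0.939, 0.798, 0.993, "beta")
  expect_equal(b$mean, 0.939, tolerance = 0.01)
  expect_equal(b$shape1 / (b$shape1 + b$shape2), 0.939, tolerance = 1e-9)
  g <- fit_distribution(85.5, 59.8, 111.1, "gamma")
  expect_equal(g$shape / g$rate, 85.5, tolerance = 1e-9)
  expect_gt(g$shape, 0)  # strictly positive support
  ln <- fit_distribution(0.79, 0.77, 0.80, "log-normal")
  expect_equal(exp(ln$meanlog + ln$sdlog^2 / 2), 0.79, tolerance = 1e-9)
  # degenerate range collapses to a point mass
  pt <- fit_distribution(5, 5, 5, "gamma")
  expect_identical(pt$family, "point")
  expect_identical(draw_from_spec(pt, 3), c(5, 5, 5))
})

test_that("infeasible or invalid ranges raise fit errors", {
  expect_error(fit_distribution(0.02, 0, 0.9, "beta"), "fit error")
  expect_error(fit_distribution(0.5, 0.6, 0.9, "beta"), "min <= baseline")
  expect_error(fit_distribution(85.5, NA, NA, "gamma"), "unsupported-parameter")
})

test_that("drawn marginals match their specs by the law of large numbers", {
  set.seed(1)
  g <- fit_distribution(85.5, 59.8, 111.1, "gamma")
  x <- draw_from_spec(g, 10000)
  expect_true(all(x > 0))
  expect_equal(mean(x), 85.5, tolerance = 0.02 * 85.5)
  b <- fit_distribution(0.939, 0.798, 0.993, "beta")
  y <- draw_from_spec(b, 10000)
  expect_true(all(y > 0 & y < 1))
  expect_equal(mean(y), 0.939, tolerance = 0.01)
})

test_that("one-way analysis brackets the baseline ICER monotonically in a cost", {
  s <- bc_strategy("annual", 1); cmp <- no_screening()
  base_icer <- compare_strategies(res_annual(), res_none(), 23050)$icer
  ow0 <- one_way("costs.treatment.I", s, cmp, base_params, base_lt,
                 lo = 10067, hi = 10067)
  expect_equal(ow0$icer_at_lo, base_icer)
  expect_equal(ow0$icer_at_hi, base_icer)
  ow <- one_way("costs.treatment.I", s, cmp, base_params, base_lt)
  expect_true(ow$icer_at_lo < base_icer && base_icer < ow$icer_at_hi)
  # false-positive disutility: finite ICERs at both published bounds
  owd <- one_way("disutility_fp", s, cmp, base_params, base_lt)
  expect_true(is.finite(owd$icer_at_lo) && is.finite(owd$icer_at_hi))
  expect_error(one_way("progression", s, cmp, base_params, base_lt),
               "unsupported-parameter")
})

test_that("PSA draws are reproducible under a seed and respect supports", {
  s <- bc_strategy("annual", 1); cmp <- no_screening()
  d1 <- run_psa(20, 42, s, cmp, base_params, base_lt)
  d2 <- run_psa(20, 42, s, cmp, base_params, base_lt)
  expect_identical(d1$draws, d2$draws)
  expect_identical(d1$samples, d2$samples)
  d3 <- run_psa(20, 43, s, cmp, base_params, base_lt)
  expect_false(identical(d1$draws, d3$draws))
  # utilities and test performance stay in [0,1]; costs stay non-negative
  for (path in colnames(d1$samples)) {
    if (startsWith(path, "costs")) {
      expect_true(all(d1$samples[, path] >= 0))
    } else {
      expect_true(all(d1$samples[, path] >= 0 & d1$samples[, path] <= 1))
    }
  }
})

test_that("the acceptability curve is a fraction of positive net benefit", {
  fake <- structure(list(draws = data.frame(
    incremental_cost = c(100, 200, 300),
    incremental_qaly = c(0.02, 0.02, 0.02))), class = "bc_psa_draws")
  expect_equal(ceac(fake, 0)$p_cost_effective, 0)      # all dC > 0
  expect_equal(ceac(fake, 1e9)$p_cost_effective, 1)    # all dE > 0
  expect_equal(ceac(fake, 7000)$p_cost_effective, 1 / 3)
  expect_error(ceac(fake, numeric(0)), "domain error")
  # NMB = 0 boundary: a draw with wtp exactly at its ICER does not count
  expect_equal(ceac(fake, 10000)$p_cost_effective, 1 / 3)
  expect_equal(ceac(fake, 10001)$p_cost_effective, 2 / 3)
})

test_that("scenario grid covers intervals and uptake, warning without mammography data", {
  expect_warning(tab <- run_scenarios(base_params, base_lt), "mammography-alone")
  expect_equal(tab$strategy,
               c("none", "annual", "every_3_years", "every_5_years",
                 "annual_70pct_treated"))
  expect_true(all(diff(tab$cost[c(1, 4, 3, 2)]) > 0))  # none < q5 < q3 < annual
  # 70% uptake is strictly less cost-effective than full-uptake annual screening
  expect_gt(tab$icer[tab$strategy == "annual_70pct_treated"],
            tab$icer[tab$strategy == "annual"])
  # full uptake reduces the 70%-uptake scenario to the baseline annual run
  res_full <- run_cohort(bc_strategy("annual_70pct_treated", 1,
                                     treatment_uptake = 1),
                         base_params, base_lt)
  expect_equal(res_full$discounted_cost, res_annual()$discounted_cost)
  expect_equal(res_full$discounted_qaly, res_annual()$discounted_qaly)
})

test_that("user-supplied mammography-alone performance unlocks the modality scenarios", {
  p <- base_params
  p$test_perf$mammo_alone <- list(sensitivity = rng3(0.80, 0.70, 0.90),
                                  specificity = rng3(0.985, 0.975, 0.995))
  expect_no_warning(tab <- run_scenarios(p, base_lt))
  expect_equal(nrow(tab), 8)
  expect_true(all(grepl("vs_mammo_alone", tab$strategy[6:8])))
})
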