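test_that("modality and test performance follow the age bands", {
  s <- bc_strategy("annual", 1)
  tc42 <- test_characteristics(42, s, base_params)
  expect_equal(tc42$sensitivity, 0.848)
  expect_equal(tc42$specificity, 0.994)
  expect_equal(tc42$modality, "us_then_mammo")
  tc50 <- test_characteristics(50, s, base_params)
  expect_equal(tc50$sensitivity, 0.939)
  expect_equal(tc50$specificity, 0.980)
  # outside the eligible range: a not-screened signal, not an error
  expect_null(test_characteristics(72, s, base_params))
  expect_null(test_characteristics(39, s, base_params))
  expect_null(test_characteristics(50, no_screening(), base_params))
})

test_that("a healthy cohort incurs screening overheads and false-positive biopsies", {
  occ <- numeric(17); occ[1] <- 1
  out <- apply_screening_round(occ, 42, bc_strategy("annual", 1), base_params)
  fp <- 1 - 0.994
  expect_equal(out$cost, 1.6 + 85.5 + fp * 45.6)
  expect_equal(out$false_positives, fp)
  expect_equal(out$disutility, fp * 0.25 * base_params$fp_duration_years)
  expect_equal(out$occupancy, occ)  # false positives do not change state
})

test_that("preclinical disease is detected at test sensitivity and treated", {
  occ <- numeric(17); occ[3] <- 1  # all mass preclinical stage I
  s <- bc_strategy("annual", 1)
  out <- apply_screening_round(occ, 42, s, base_params)
  expect_equal(out$occupancy[8], 0.848)          # treated stage I
  expect_equal(out$occupancy[3], 1 - 0.848)
  expect_equal(out$cost, 1.6 + 85.5 + 0.848 * (45.6 + 10067))
  expect_equal(unname(out$detected[["I"]]), 0.848)
  # with partial uptake, the undetected-treatment fraction is diagnosed untreated
  s70 <- bc_strategy("a70", 1, treatment_uptake = 0.7)
  out70 <- apply_screening_round(occ, 42, s70, base_params)
  expect_equal(out70$occupancy[8], 0.848 * 0.7)
  expect_equal(out70$occupancy[12], 0.848 * 0.3)
})

test_that("an inert test leaves the cohort unchanged apart from overheads", {
  p <- base_params
  p$test_perf$us_then_mammo$sensitivity[["baseline"]] <- 0
  p$test_perf$us_then_mammo$specificity[["baseline"]] <- 1
  occ <- numeric(17); occ[1] <- 0.6; occ[3] <- 0.3; occ[16] <- 0.1
  out <- apply_screening_round(occ, 42, bc_strategy("annual", 1), p)
  expect_equal(out$occupancy, occ)
  expect_equal(out$cost, 0.9 * (1.6 + 85.5))
  expect_equal(out$disutility, 0)
})

test_that("screening conserves cohort mass and costs behave monotonically", {
  set.seed(7)
  s <- bc_strategy("annual", 1)
  for (i in 1:10) {
    occ <- stats::runif(17); occ <- occ / sum(occ)
    out <- apply_screening_round(occ, 50, s, base_params)
    expect_equal(sum(out$occupancy), sum(occ), tolerance = 1e-12)
  }
  # lower specificity -> more false-positive biopsies -> higher cost
  occ <- numeric(17); occ[1] <- 1
  p_lo <- base_params
  p_lo$test_perf$us_then_mammo$specificity[["baseline"]] <- 0.90
  expect_gt(apply_screening_round(occ, 42, s, p_lo)$cost,
            apply_screening_round(occ, 42, s, base_params)$cost)
  # higher disease prevalence -> more biopsies and treatments -> higher cost
  occ_sick <- numeric(17); occ_sick[1] <- 0.5; occ_sick[3] <- 0.5
  expect_gt(apply_screening_round(occ_sick, 42, s, base_params)$cost,
            apply_screening_round(occ, 42, s, base_params)$cost)
})

test_that("rounds fire on the strategy's interval grid", {
  q3 <- bc_strategy("q3", 3)
  expect_true(screening_due(40, q3))
  expect_false(screening_due(41, q3))
  expect_true(screening_due(43, q3))
  expect_false(screening_due(70, q3))
  expect_false(screening_due(50, no_screening()))
})
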