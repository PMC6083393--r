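test_that("discount factors follow 1/(1+r)^t", {
  expect_equal(discount_factor(0, 0.03), 1)
  expect_equal(discount_factor(0:5, 0), rep(1, 6))
  expect_equal(discount_factor(1, 0.03), 1 / 1.03)
  expect_equal(discount_factor(10, 0.03), 1.03^-10)
  expect_error(discount_factor(-1, 0.03), "domain error")
})

test_that("a disease-free cohort reproduces discounted life expectancy exactly", {
  p0 <- bc_parameters(incidence_by_age = 0 * DEFAULT_INCIDENCE)
  res <- run_cohort(no_screening(), p0, base_lt)
  expect_equal(res$discounted_qaly, discounted_le(base_lt, 0.03),
               tolerance = 1e-9)
  expect_equal(res$undiscounted_qaly, discounted_le(base_lt, 0), tolerance = 1e-9)
  expect_equal(res$discounted_cost, 0)
  expect_equal(unname(res$counts_per_1000), c(0, 0, 0))
})

test_that("zero discounting collapses discounted and undiscounted outputs", {
  p <- bc_parameters(discount_rate = 0)
  res <- run_cohort(no_screening(), p, base_lt)
  expect_equal(res$discounted_cost, res$undiscounted_cost)
  expect_equal(res$discounted_qaly, res$undiscounted_qaly)
})

test_that("occupancy mass is conserved at every cycle", {
  for (res in list(res_none(), res_annual(), res_a70())) {
    expect_lt(max(abs(rowSums(res$trace) - 1)), 1e-12)
    expect_true(all(res$trace >= 0))
  }
})

test_that("discounting can only shrink lifetime totals", {
  for (res in list(res_none(), res_annual(), res_q3(), res_q5())) {
    expect_lte(res$discounted_cost, res$undiscounted_cost)
    expect_lte(res$discounted_qaly, res$undiscounted_qaly)
  }
})

test_that("screening adds both cost and health benefit over no screening", {
  expect_gt(res_annual()$discounted_cost, res_none()$discounted_cost)
  expect_gt(res_annual()$discounted_qaly, res_none()$discounted_qaly)
})

test_that("shorter screening intervals cost more and yield more QALYs", {
  costs <- c(res_annual()$discounted_cost, res_q3()$discounted_cost,
             res_q5()$discounted_cost, res_none()$discounted_cost)
  qalys <- c(res_annual()$discounted_qaly, res_q3()$discounted_qaly,
             res_q5()$discounted_qaly, res_none()$discounted_qaly)
  expect_true(all(diff(costs) < 0))
  expect_true(all(diff(qalys) < 0))
})

test_that("event counts are coherent", {
  for (res in list(res_none(), res_annual(), res_q3())) {
    cts <- res$counts_per_1000
    expect_true(all(cts >= 0))
    expect_lte(cts[["screen_detected"]] + cts[["symptom_detected"]],
               cts[["incident"]] + 1e-9)
  }
  expect_equal(res_none()$counts_per_1000[["screen_detected"]], 0)
  # most detections shift from symptomatic to screen-detected under screening
  expect_lt(res_annual()$counts_per_1000[["symptom_detected"]],
            res_none()$counts_per_1000[["symptom_detected"]])
})

test_that("the occupancy trace can be written out for inspection", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(res_none(), f)
  df <- utils::read.csv(f, check.names = FALSE)
  expect_equal(nrow(df), 61)
  expect_equal(names(df), c("age", health_states()))
})
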