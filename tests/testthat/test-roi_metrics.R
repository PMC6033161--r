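test_that("package evaluation reproduces the illustrative building blocks", {
  res <- worked_example_results()

  expect_equal(res$status_quo$quitters, 20)
  expect_equal(res$status_quo$intervention_cost_total, 0)

  expect_equal(res$attempt_boost$quitters, 25)
  expect_equal(res$attempt_boost$intervention_cost_total, 40000)

  expect_equal(res$novel_aid$quitters, 21)
  # 400 attempters * 20% uptake * 225 per use
  expect_equal(res$novel_aid$intervention_cost_total, 18000)

  expect_equal(res$novel_aid_promoted$quitters, 22)
  expect_equal(res$novel_aid_promoted$intervention_cost_total,
               0.4 * 400 * 225 + 50000)

  # convex combination of per-smoker outcomes
  expect_equal(res$status_quo$expected_qalys, 20 * 15.86 + 1980 * 14.77)
  expect_equal(res$status_quo$expected_cost, 20 * 9602 + 1980 * 14563)
})

test_that("comparisons yield the published ICERs and consistent metrics", {
  comps <- worked_example_comparisons()
  expect_equal(comps$attempt_boost$icer_rounded, 2788)
  expect_equal(comps$novel_aid$icer_rounded, 11962)
  expect_equal(comps$novel_aid_promoted$icer_rounded, 57834)

  c1 <- comps$attempt_boost
  expect_equal(c1$delta_qalys, 5 * 1.09, tolerance = 1e-9)
  expect_equal(c1$delta_cost, 40000 - 5 * 4961, tolerance = 1e-9)
  expect_equal(c1$nmb, c1$threshold * c1$delta_qalys - c1$delta_cost)
  # benefit-cost ratio consistency with NMB
  d_ic <- 40000
  expect_equal(c1$bcr, c1$nmb / d_ic + 1, tolerance = 1e-12)
})

test_that("self-comparison gives zero deltas and an undefined ICER", {
  res <- worked_example_results()
  same <- compare_packages(res$status_quo, res$status_quo)
  expect_equal(same$delta_cost, 0)
  expect_equal(same$delta_qalys, 0)
  expect_true(is.na(same$icer))
  expect_identical(same$icer_label, "undefined")
  expect_equal(same$nmb, 0)
})

test_that("NMB is linear in the threshold and crosses zero at the ICER", {
  res <- worked_example_results()
  cmp <- function(l) compare_packages(res$status_quo, res$novel_aid,
                                      threshold = l)
  icer <- cmp(0)$icer
  expect_equal(cmp(icer)$nmb, 0, tolerance = 1e-6)
  expect_lt(cmp(icer - 1000)$nmb, 0)
  expect_gt(cmp(icer + 1000)$nmb, 0)
  # linearity
  n0 <- cmp(0)$nmb
  n1 <- cmp(10000)$nmb
  n2 <- cmp(20000)$nmb
  expect_equal(n2 - n1, n1 - n0, tolerance = 1e-9)
})

test_that("dominance labels follow the cost-QALY quadrant", {
  mk <- function(cost, qalys) {
    structure(list(package = list(name = "x"), horizon = "lifetime",
                   discounted = TRUE, n_smokers = 1, quit_prob = 0,
                   attempters = 0, quitters = 0,
                   intervention_cost_total = 0, expected_cost = cost,
                   expected_qalys = qalys, expected_life_years = NA_real_,
                   expected_deaths = NA_real_),
              class = "package_result")
  }
  a <- mk(1000, 10)
  expect_identical(compare_packages(a, mk(900, 10.5))$icer_label, "dominant")
  expect_identical(compare_packages(a, mk(1100, 9.5))$icer_label,
                   "dominated")
  expect_identical(compare_packages(a, mk(1100, 10.5))$icer_label, "")
  expect_true(is.na(compare_packages(a, mk(900, 9.5))$icer))
})

test_that("deaths averted flow through from full scenario outcomes", {
  ds <- tiny_fixture()
  out <- run_scenarios(ds)
  we <- england_worked_example()
  sq <- evaluate_package(we$packages$status_quo, out)
  boost <- evaluate_package(we$packages$attempt_boost, out)
  cmp <- compare_packages(sq, boost, threshold = 20000)
  # more quitters -> fewer deaths at the lifetime horizon
  expect_gt(cmp$deaths_averted, 0)
  expect_equal(cmp$deaths_averted,
               (boost$quitters - sq$quitters) *
                 -diff(c(out$population$p_dead[
                   out$population$scenario == "no_quit_first_cycle" &
                     out$population$horizon == "lifetime" &
                     out$population$discounted],
                   out$population$p_dead[
                     out$population$scenario == "quit_first_cycle" &
                       out$population$horizon == "lifetime" &
                       out$population$discounted])),
               tolerance = 1e-9)
})
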