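test_that("the comorbidity decrement expectation matches enumeration", {
  expect_equal(expected_disease_decrement(numeric(0), numeric(0)), 0)
  expect_equal(expected_disease_decrement(c(0, 0), c(0.3, 0.1)), 0)
  expect_equal(expected_disease_decrement(0.1, 0.2), 0.02)
  # two diseases: 0.1*0.3 + 0.9*0.2*0.1 = 0.048
  expect_equal(expected_disease_decrement(c(0.1, 0.2), c(0.3, 0.1)), 0.048,
               tolerance = 1e-12)
  # order of supplied diseases must not matter
  expect_equal(expected_disease_decrement(c(0.2, 0.1), c(0.1, 0.3)), 0.048,
               tolerance = 1e-12)

  set.seed(11)
  for (i in 1:20) {
    prev <- stats::runif(4, 0, 0.4)
    dec <- stats::runif(4, 0, 0.3)
    expect_equal(expected_disease_decrement(prev, dec),
                 enumerate_max_decrement(prev, dec), tolerance = 1e-12)
  }
})

test_that("cycle utility subtracts the expected decrement and floors at 0", {
  ds <- small_fixture()
  ut <- ds$utilities
  expect_equal(cycle_utility("former", ut, rep(0, 4)), ut$u_former$value)
  single <- ut
  single$u_former$value <- 0.85
  single$decrements$decrement <- c(0.2, 0, 0, 0)
  expect_equal(cycle_utility("former", single, c(0.5, 0, 0, 0)), 0.75)
  crushing <- ut
  crushing$decrements$decrement <- rep(2, 4)
  expect_equal(cycle_utility("current", crushing, c(1, 0, 0, 0)), 0)
})

test_that("cycle cost is additive across diseases", {
  econ <- data.frame(disease = roi_diseases,
                     annual_cost = c(10000, 4000, 0, 0),
                     se = 0)
  expect_equal(cycle_cost(rep(0, 4), econ), 0)
  expect_equal(cycle_cost(c(0.05, 0, 0, 0), econ), 500)
  expect_equal(cycle_cost(c(0.05, 0.02, 0, 0), econ), 580)
})

test_that("discounting follows the cycle-1-at-face-value convention", {
  expect_equal(discount_factor(0, 1:10), rep(1, 10))
  expect_equal(discount_factor(0.07, 1), 1)
  expect_equal(discount_factor(0.035, 2), 1 / 1.035, tolerance = 1e-12)
  expect_equal(discount_factor(0.035, 4), 1.035^-3, tolerance = 1e-12)
})

test_that("accumulation matches closed forms on a degenerate dataset", {
  ds <- small_fixture()
  ds$life_table$p_death <- 0
  ds$disease_prevalence$prev_all <- 0
  tr <- run_cohort(60, "female", "quit_first_cycle", ds, q_net = 0)
  po <- accumulate_outcomes(tr, ds)
  u <- ds$utilities$u_former$value

  two_u <- po[po$horizon == "2" & !po$discounted, ]
  expect_equal(two_u$life_years, 2)
  expect_equal(two_u$qalys, 2 * u, tolerance = 1e-12)
  expect_equal(two_u$cost, 0)

  two_d <- po[po$horizon == "2" & po$discounted, ]
  expect_equal(two_d$life_years, 1 + 1 / 1.035, tolerance = 1e-12)
  expect_equal(two_d$qalys, (1 + 1 / 1.035) * u, tolerance = 1e-12)
})

test_that("accumulation agrees with the scalar primitives cycle by cycle", {
  ds <- small_fixture()
  ds$settings$horizons <- c("2", "lifetime")
  tr <- run_cohort(98, "male", "no_quit_first_cycle", ds)  # 3 cycles
  po <- accumulate_outcomes(tr, ds)
  sdp <- status_disease_prevalence(ds)
  r <- ds$settings$discount_rate

  manual <- c(cost = 0, qalys = 0, ly = 0)
  manual_disc <- manual
  for (t in 1:3) {
    age <- 97 + t
    prev_c <- sapply(roi_diseases, function(d) {
      sdp$prev_current[sdp$disease == d & sdp$sex == "male" &
                         sdp$age == age]
    })
    prev_f <- sapply(roi_diseases, function(d) {
      sdp$prev_former[sdp$disease == d & sdp$sex == "male" &
                        sdp$age == age]
    })
    econ <- ds$disease_costs[match(roi_diseases, ds$disease_costs$disease), ]
    sc <- tr$occupancy[t, "s_current"]
    sf <- tr$occupancy[t, "s_former"]
    flows <- c(
      cost = sc * cycle_cost(prev_c, econ) + sf * cycle_cost(prev_f, econ),
      qalys = sc * cycle_utility("current", ds$utilities, prev_c) +
        sf * cycle_utility("former", ds$utilities, prev_f),
      ly = sc + sf)
    manual <- manual + flows
    manual_disc <- manual_disc + flows * discount_factor(r, t)
  }
  life_u <- po[po$horizon == "lifetime" & !po$discounted, ]
  life_d <- po[po$horizon == "lifetime" & po$discounted, ]
  expect_equal(life_u$cost, unname(manual["cost"]), tolerance = 1e-9)
  expect_equal(life_u$qalys, unname(manual["qalys"]), tolerance = 1e-9)
  expect_equal(life_u$life_years, unname(manual["ly"]), tolerance = 1e-9)
  expect_equal(life_d$cost, unname(manual_disc["cost"]), tolerance = 1e-9)
  expect_equal(life_d$qalys, unname(manual_disc["qalys"]), tolerance = 1e-9)
})

test_that("outcomes are monotone in horizon and bounded by discounting", {
  ds <- small_fixture()
  tr <- run_cohort(60, "male", "no_quit_first_cycle", ds)
  po <- accumulate_outcomes(tr, ds)
  for (disc in c(TRUE, FALSE)) {
    sl <- po[po$discounted == disc, ]
    sl <- sl[match(c("2", "5", "10", "lifetime"), sl$horizon), ]
    for (col in c("cost", "life_years", "qalys")) {
      expect_true(all(diff(sl[[col]]) >= 0))
    }
  }
  merged <- merge(po[po$discounted, ], po[!po$discounted, ], by = "horizon")
  expect_true(all(merged$cost.x <= merged$cost.y))
  expect_true(all(merged$qalys.x <= merged$qalys.y))
  expect_true(all(po$life_years >= po$qalys))
})

test_that("a horizon longer than the trace warns and truncates", {
  ds <- small_fixture()
  ds$settings$horizons <- c("5", "lifetime")
  tr <- run_cohort(99, "male", "no_quit_first_cycle", ds)  # 2 cycles
  expect_warning(po <- accumulate_outcomes(tr, ds), "truncated")
  expect_equal(po$cost[po$horizon == "5" & po$discounted],
               po$cost[po$horizon == "lifetime" & po$discounted])
})

test_that("population weighting is a weighted mean plus death counts", {
  tmpl <- data.frame(
    sex = c("male", "male"), start_age = c(60, 61),
    scenario = "no_quit_first_cycle", horizon = "lifetime",
    discounted = TRUE, cost = c(10, 20), life_years = c(1, 2),
    qalys = c(1, 3), p_dead = c(0.5, 0.9))
  popn <- data.frame(sex = c("male", "male"), age = c(60, 61),
                     n_smokers = c(1, 3))
  w <- weight_population(tmpl, popn)
  expect_equal(w$cost, 17.5)
  expect_equal(w$qalys, 2.5)
  expect_equal(w$deaths, 0.5 + 3 * 0.9)

  single <- weight_population(tmpl[1, ], popn[1, ])
  expect_equal(single$cost, 10)
  expect_equal(single$p_dead, 0.5)

  popn0 <- popn
  popn0$n_smokers <- 0
  expect_error(weight_population(tmpl, popn0), "zero")
})
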