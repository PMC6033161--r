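test_that("mortality decomposition matches hand arithmetic", {
  # denominator 0.5 + 0.2*1.3 + 0.3*2.0 = 1.36
  r <- mortality_by_status(0.02, 0.5, 0.2, 0.3,
                           rr_former = 1.3, rr_current = 2.0)
  expect_equal(r$p_never, 0.02 / 1.36, tolerance = 1e-12)
  expect_equal(r$p_former, 1.3 * 0.02 / 1.36, tolerance = 1e-12)
  expect_equal(r$p_current, 2.0 * 0.02 / 1.36, tolerance = 1e-12)

  # never-smokers only: p_never equals the population value
  r2 <- mortality_by_status(0.01, 1, 0, 0, rr_former = 1.5, rr_current = 3)
  expect_equal(r2$p_never, 0.01)
  expect_equal(r2$p_former, 0.015)
  expect_equal(r2$p_current, 0.03)

  # no differential risk: all three equal the population value
  r3 <- mortality_by_status(0.07, 0.3, 0.3, 0.4, 1, 1)
  expect_equal(unlist(r3), c(p_never = 0.07, p_former = 0.07,
                             p_current = 0.07))

  expect_error(mortality_by_status(0.02, 0, 0, 0, 1.3, 2), "denominator")
})

test_that("disease decomposition applies the under-35 equal-risk rule", {
  r <- disease_prevalence_by_status(0.001, 0.5, 0.2, 0.3, 4, 8, age = 30)
  expect_equal(unlist(r), c(prev_never = 0.001, prev_former = 0.001,
                            prev_current = 0.001))

  r50 <- disease_prevalence_by_status(0.05, 0.5, 0.2, 0.3, 1, 1, age = 50)
  expect_equal(unname(unlist(r50)), rep(0.05, 3))

  # age 60, denominator 0.5 + 0.3*2 + 0.2*4 = 1.9
  r60 <- disease_prevalence_by_status(0.05, 0.5, 0.3, 0.2,
                                      rr_former = 2, rr_current = 4,
                                      age = 60)
  expect_equal(r60$prev_never, 0.05 / 1.9, tolerance = 1e-12)
  expect_equal(r60$prev_former, 0.1 / 1.9, tolerance = 1e-12)
  expect_equal(r60$prev_current, 0.2 / 1.9, tolerance = 1e-12)
})

test_that("decompositions agree with an independent linear solve", {
  set.seed(42)
  for (i in 1:25) {
    pis <- as.vector(stats::rmultinom(1, 1000, c(0.5, 0.25, 0.25))) / 1000
    rrf <- stats::runif(1, 1, 3)
    rrc <- stats::runif(1, 1, 6)
    p_all <- stats::runif(1, 0, 0.2)
    r <- mortality_by_status(p_all, pis[1], pis[2], pis[3], rrf, rrc)
    # one-unknown linear system solved independently
    x <- as.numeric(solve(matrix(pis[1] + pis[2] * rrf + pis[3] * rrc),
                          p_all))
    expect_equal(r$p_never, x, tolerance = 1e-12)
    # consistency: status-weighted mean reproduces the population value
    expect_equal(pis[1] * r$p_never + pis[2] * r$p_former +
                   pis[3] * r$p_current, p_all, tolerance = 1e-9)
  }
})

test_that("derived tables stay consistent with population inputs", {
  ds <- small_fixture()
  sm <- merge(status_mortality(ds), ds$smoking_prevalence,
              by = c("sex", "age"))
  recon <- sm$pi_never * sm$p_never + sm$pi_former * sm$p_former +
    sm$pi_current * sm$p_current
  lt <- merge(sm[, c("sex", "age")], ds$life_table, by = c("sex", "age"))
  expect_equal(recon, lt$p_death, tolerance = 1e-9)

  sdp <- merge(status_disease_prevalence(ds), ds$smoking_prevalence,
               by = c("sex", "age"))
  sdp <- merge(sdp, ds$disease_prevalence, by = c("disease", "sex", "age"))
  old <- sdp[sdp$age >= 35, ]
  recon_d <- old$pi_never * old$prev_never + old$pi_former * old$prev_former +
    old$pi_current * old$prev_current
  expect_equal(recon_d, old$prev_all, tolerance = 1e-9)
})

test_that("status-specific outputs are monotone in relative risk", {
  base <- mortality_by_status(0.03, 0.4, 0.3, 0.3, 1.2, 1.8)
  higher <- mortality_by_status(0.03, 0.4, 0.3, 0.3, 1.2, 2.6)
  expect_gt(higher$p_current, base$p_current)
  expect_true(base$p_never <= base$p_former &&
                base$p_former <= base$p_current)
})

test_that("probabilities above 1 after scaling are capped with a warning", {
  expect_warning(r <- mortality_by_status(0.5, 0.9, 0, 0.1, 1.5, 10),
                 "capped")
  expect_lte(max(unlist(r)), 1)
})

test_that("first-cycle quit probability reproduces the illustrative cases", {
  we <- england_worked_example()
  expect_equal(first_cycle_quit_probability(we$packages$status_quo), 0.01)
  expect_equal(first_cycle_quit_probability(we$packages$attempt_boost),
               0.0125)
  # 0.20 * (0.20 * 0.0625 + 0.80 * 0.05)
  expect_equal(first_cycle_quit_probability(we$packages$novel_aid), 0.0105)
  expect_equal(first_cycle_quit_probability(we$packages$novel_aid_promoted),
               0.011)

  too_good <- package_spec(
    "miracle",
    interventions = list(intervention("m", uptake = 0.1, rr_success = 30)),
    baseline_attempt_rate = 0.2, unaided_success = 0.05)
  expect_error(first_cycle_quit_probability(too_good), "success")
})

test_that("net quit probability comes from the settings", {
  expect_equal(net_quit_probability(analysis_settings()), 0.02)
  hungary <- analysis_settings(underlying_quit_rate = 0.01)
  expect_equal(net_quit_probability(hungary), 0.01)
  expect_equal(net_quit_probability(
    analysis_settings(underlying_quit_rate = 0)), 0)
  expect_equal(net_quit_probability(small_fixture()), 0.02)
})
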