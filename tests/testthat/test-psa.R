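test_that("distribution families follow the parameter-class rules", {
  ds <- tiny_fixture()
  d <- assign_distributions(ds)
  fam <- function(id) d$family[d$id == id]
  expect_identical(fam("rr_death_current"), "lognormal")
  expect_identical(fam("rr_lung_cancer_former"), "lognormal")
  expect_identical(fam("cost_copd"), "gamma")
  expect_identical(fam("u_former"), "beta")
  expect_identical(fam("decrement_stroke"), "normal")
  # intervention and population-level quantities are not sampled at all
  expect_false(any(grepl("n_smokers|attempt|uptake|discount|quit_rate",
                         d$id)))
  expect_identical(d$id, sort(d$id))
})

test_that("gamma moment matching gives the textbook shape and rate", {
  # point 1000, se 200 -> shape 25, rate 0.025
  d <- structure(
    data.frame(id = "cost_x", family = "gamma", mean = 1000, se = 200),
    class = c("parameter_distributions", "data.frame"))
  set.seed(1)
  x <- sample_parameters(d, 200000)[, 1]
  expect_equal(mean(x), 1000, tolerance = 0.005)
  expect_equal(stats::sd(x), 200, tolerance = 0.01)
  # the implied gamma parameters themselves
  expect_equal((1000 / 200)^2, 25)
  expect_equal(1000 / 200^2, 0.025)
})

test_that("zero standard errors degenerate to fixed with a warning", {
  ds <- tiny_fixture()
  ds$utilities$u_never$se <- 0
  expect_warning(d <- assign_distributions(ds), "u_never")
  expect_identical(d$family[d$id == "u_never"], "fixed")
  set.seed(1)
  expect_equal(unique(sample_parameters(d[d$id == "u_never", ], 5)[, 1]),
               ds$utilities$u_never$value)
})

test_that("a beta standard error outside the support is rejected", {
  ds <- tiny_fixture()
  ds$utilities$u_current$se <- 0.9
  expect_error(assign_distributions(ds), "infeasible.*u_current")
})

test_that("sampled parameters recover their moments", {
  ds <- tiny_fixture()
  d <- assign_distributions(ds)
  active <- d[d$family != "fixed", ]
  n <- 10000
  set.seed(99)
  x <- sample_parameters(active, n)
  for (j in seq_len(nrow(active))) {
    fam <- active$family[j]
    m <- active$mean[j]
    s <- active$se[j]
    draws <- x[, j]
    if (fam == "lognormal") {
      # parameterised on the log scale: check the log moments
      draws <- log(draws)
      m <- log(m)
    }
    mc_se <- stats::sd(draws) / sqrt(n)
    expect_lt(abs(mean(draws) - m), 3 * mc_se)
    sd_se <- stats::sd(draws) / sqrt(2 * (n - 1))  # normal-theory SE of sd
    expect_lt(abs(stats::sd(draws) - s), 4 * sd_se)
  }
})

test_that("PSA replicates are reproducible and sized as requested", {
  ds <- tiny_fixture()
  we <- england_worked_example()
  pks <- list(we$packages$status_quo, we$packages$novel_aid)
  r1 <- run_psa(ds, pks, n_reps = 5, seed = 123)
  r2 <- run_psa(ds, pks, n_reps = 5, seed = 123)
  expect_identical(r1$delta_cost, r2$delta_cost)
  expect_identical(r1$delta_qalys, r2$delta_qalys)
  expect_identical(nrow(r1), 5L)
  r3 <- run_psa(ds, pks, n_reps = 5, seed = 124)
  expect_false(identical(r1$delta_cost, r3$delta_cost))
  # default replication count is 1000
  expect_equal(eval(formals(run_psa)$n_reps), 1000)
})

test_that("with all parameters fixed the PSA equals the deterministic run", {
  ds <- all_fixed_fixture()
  we <- england_worked_example()
  pks <- list(we$packages$status_quo, we$packages$attempt_boost)
  reps <- suppressWarnings(run_psa(ds, pks, n_reps = 2, seed = 7))

  out <- run_scenarios(ds)
  base <- evaluate_package(pks[[1]], out)
  alt <- evaluate_package(pks[[2]], out)
  expect_identical(reps$delta_cost,
                   rep(alt$expected_cost - base$expected_cost, 2))
  expect_identical(reps$delta_qalys,
                   rep(alt$expected_qalys - base$expected_qalys, 2))
})

test_that("the CEAC is an exhaustive count over replicates", {
  reps <- data.frame(
    rep = 1:4, comparison = "b vs a",
    delta_cost = c(-100, 500, 1500, 3000),
    delta_qalys = c(0.1, 0.1, 0.1, 0.1))
  cc <- ceac(reps, thresholds = c(0, 10000, 20000, 40000))
  # NMB > 0 for: 1 | 1,2 | 1,2,3 | all
  expect_equal(cc$prob_cost_effective, c(0.25, 0.5, 0.75, 1))
  # monotone in the threshold when all QALY gains are non-negative
  expect_true(all(diff(cc$prob_cost_effective) >= 0))
  # at threshold 0 the CEAC is the cost-saving fraction
  expect_equal(cc$prob_cost_effective[cc$threshold == 0],
               mean(reps$delta_cost < 0))
  # ties count as not cost-effective
  tie <- data.frame(rep = 1, comparison = "b vs a",
                    delta_cost = 1000, delta_qalys = 0.1)
  expect_equal(ceac(tie, thresholds = 10000)$prob_cost_effective, 0)
  expect_equal(ceac(tie, thresholds = 10001)$prob_cost_effective, 1)
  # all dominant -> probability 1 everywhere
  dom <- data.frame(rep = 1:3, comparison = "b vs a",
                    delta_cost = -1, delta_qalys = 0.1)
  expect_true(all(ceac(dom)$prob_cost_effective == 1))
})

test_that("scatter export carries one row per replicate plus means", {
  ds <- tiny_fixture()
  we <- england_worked_example()
  reps <- run_psa(ds, list(we$packages$status_quo, we$packages$novel_aid),
                  n_reps = 8, seed = 2)
  sc <- export_scatter(reps)
  expect_identical(nrow(sc), 8L)
  s <- attr(sc, "summary")
  expect_equal(s$mean_delta_cost, mean(sc$delta_cost))
  expect_equal(s$mean_delta_qalys, mean(sc$delta_qalys))
})
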