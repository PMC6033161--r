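# Decision metrics: package evaluation on scenario outcomes, incremental
# cost-effectiveness, net monetary benefit, benefit-cost ratio, deaths
# averted.

round_currency <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Evaluate an intervention package on scenario outcomes
#'
#' Combines the quit and no-quit per-smoker outcomes as a convex
#' combination weighted by the package's first-cycle quit probability, adds
#' intervention costs, and scales to the population:
#' `quitters = n * quit_prob`, `attempters = n * A_eff`,
#' `intervention_cost = sum_i fixed_i + uptake_i * attempters * cost_per_use_i`.
#'
#' @param package A [package_spec()].
#' @param outcomes Either a `scenario_outcomes` from [run_scenarios()] or a
#'   list `list(quit = ..., no_quit = ...)` whose elements carry per-smoker
#'   `cost`, `qalys` and optionally `life_years` and `p_dead` — the latter
#'   form lets published per-smoker lifetime estimates drive the metrics
#'   directly.
#' @param n_smokers Smoking population size; defaults to the total in
#'   `outcomes` when it is a `scenario_outcomes`.
#' @param horizon,discounted Which outcome slice to use when `outcomes` is a
#'   `scenario_outcomes`.
#' @return A `package_result` list: `quit_prob`, `attempters`, `quitters`,
#'   `intervention_cost_total`, `expected_cost`, `expected_qalys`,
#'   `expected_life_years`, `expected_deaths` (NA when `p_dead` absent).
#' @examples
#' we <- england_worked_example()
#' evaluate_package(we$packages$status_quo, we$outcomes, n_smokers = 2000)
#' @export
evaluate_package <- function(package, outcomes, n_smokers = NULL,
                             horizon = "lifetime", discounted = TRUE) {
  stopifnot(inherits(package, "package_spec"))
  if (inherits(outcomes, "scenario_outcomes")) {
    if (is.null(n_smokers)) n_smokers <- outcomes$n_smokers
    pop <- outcomes$population
    pick <- function(scn) {
      row <- pop[pop$scenario == scn & pop$horizon == horizon &
                   pop$discounted == discounted, ]
      if (nrow(row) != 1) {
        roi_abort("no population outcome row for scenario ", scn,
                  ", horizon ", horizon, ", discounted ", discounted)
      }
      as.list(row)
    }
    qo <- pick("quit_first_cycle")
    nq <- pick("no_quit_first_cycle")
  } else {
    if (is.null(n_smokers)) roi_abort("n_smokers required with raw outcomes")
    qo <- outcomes$quit
    nq <- outcomes$no_quit
  }

  quit_prob <- first_cycle_quit_probability(package)
  a_eff <- effective_attempt_rate(package)
  attempters <- n_smokers * a_eff
  ic <- sum(vapply(package$interventions, function(iv) {
    iv$fixed_cost + iv$uptake * attempters * iv$cost_per_use
  }, numeric(1)))

  quitters <- n_smokers * quit_prob
  stayers <- n_smokers - quitters
  mix <- function(field) {
    a <- qo[[field]]; b <- nq[[field]]
    if (is.null(a) || is.null(b)) return(NA_real_)
    quitters * a + stayers * b
  }
  structure(
    list(package = package, horizon = horizon, discounted = discounted,
         n_smokers = n_smokers, quit_prob = quit_prob,
         attempters = attempters, quitters = quitters,
         intervention_cost_total = ic,
         expected_cost = mix("cost") + ic,
         expected_qalys = mix("qalys"),
         expected_life_years = mix("life_years"),
         expected_deaths = mix("p_dead")),
    class = "package_result"
  )
}

#' @export
print.package_result <- function(x, ...) {
  cat("<package_result> ", x$package$name, " (horizon ", x$horizon,
      if (x$discounted) ", discounted" else ", undiscounted", ")\n", sep = "")
  cat(sprintf("  quit probability %.4f -> %.1f quitters of %s smokers\n",
              x$quit_prob, x$quitters, format(x$n_smokers)))
  cat(sprintf("  intervention cost %.2f; expected cost %.2f; QALYs %.2f\n",
              x$intervention_cost_total, x$expected_cost, x$expected_qalys))
  invisible(x)
}

#' Compare two package results
#'
#' Incremental metrics of `b` relative to `a`: `delta_cost`, `delta_qalys`,
#' the ICER (`delta_cost / delta_qalys`, reported when `delta_qalys > 0`),
#' dominance labels, net monetary benefit `nmb = threshold * delta_qalys -
#' delta_cost`, a benefit-cost ratio, and deaths averted
#' (`deaths_a - deaths_b`). The benefit-cost ratio is defined as monetised
#' QALY gain plus healthcare cost savings, divided by the incremental
#' intervention spend.
#'
#' @param a,b `package_result` objects on the same population and horizon.
#' @param threshold Willingness to pay per QALY.
#' @return A `roi_comparison` list. `icer` is the unrounded ratio (`NA` when
#'   `delta_qalys <= 0`); `icer_rounded` rounds to whole currency units,
#'   half away from zero; `icer_label` is `"dominant"`, `"dominated"`,
#'   `"undefined"` or `""`.
#' @examples
#' we <- england_worked_example()
#' sq <- evaluate_package(we$packages$status_quo, we$outcomes, 2000)
#' e1 <- evaluate_package(we$packages$attempt_boost, we$outcomes, 2000)
#' compare_packages(sq, e1, threshold = 20000)
#' @export
compare_packages <- function(a, b, threshold = 20000) {
  stopifnot(inherits(a, "package_result"), inherits(b, "package_result"))
  if (a$horizon != b$horizon || a$discounted != b$discounted ||
      a$n_smokers != b$n_smokers) {
    roi_abort("package results must share population, horizon and discounting")
  }
  dc <- b$expected_cost - a$expected_cost
  dq <- b$expected_qalys - a$expected_qalys
  icer <- if (dq > 0) dc / dq else NA_real_
  label <- if (dc < 0 && dq > 0) "dominant"
           else if (dc > 0 && dq < 0) "dominated"
           else if (dq == 0) "undefined"
           else ""
  nmb <- threshold * dq - dc
  hc_savings <- (a$expected_cost - a$intervention_cost_total) -
    (b$expected_cost - b$intervention_cost_total)
  d_ic <- b$intervention_cost_total - a$intervention_cost_total
  bcr <- if (d_ic > 0) (threshold * dq + hc_savings) / d_ic else NA_real_
  structure(
    list(a = a$package$name, b = b$package$name,
         horizon = a$horizon, discounted = a$discounted,
         threshold = threshold,
         delta_cost = dc, delta_qalys = dq,
         delta_life_years = b$expected_life_years - a$expected_life_years,
         icer = icer,
         icer_rounded = if (is.na(icer)) NA_real_ else round_currency(icer),
         icer_label = label,
         nmb = nmb, bcr = bcr,
         deaths_averted = a$expected_deaths - b$expected_deaths),
    class = "roi_comparison"
  )
}

#' @export
print.roi_comparison <- function(x, ...) {
  cat("<roi_comparison> ", x$b, " vs ", x$a, " (horizon ", x$horizon, ")\n",
      sep = "")
  cat(sprintf("  incremental cost %.2f, incremental QALYs %.4f\n",
              x$delta_cost, x$delta_qalys))
  if (!is.na(x$icer)) {
    cat(sprintf("  ICER %s per QALY%s\n", format(x$icer_rounded),
                if (x$icer_label == "dominant") " (dominant)" else ""))
  } else {
    cat("  ICER ", if (nzchar(x$icer_label)) x$icer_label else "not defined",
        "\n", sep = "")
  }
  cat(sprintf("  NMB at threshold %s: %.2f", format(x$threshold), x$nmb))
  if (!is.na(x$bcr)) cat(sprintf("; benefit-cost ratio %.2f", x$bcr))
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.roi_comparison <- function(x, ...) {
  data.frame(a = x$a, b = x$b, horizon = x$horizon,
             discounted = x$discounted, threshold = x$threshold,
             delta_cost = x$delta_cost, delta_qalys = x$delta_qalys,
             delta_life_years = x$delta_life_years,
             icer = x$icer, icer_rounded = x$icer_rounded,
             icer_label = x$icer_label, nmb = x$nmb, bcr = x$bcr,
             deaths_averted = x$deaths_averted)
}
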