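# Three-state annual-cycle cohort engine: current smoker, former smoker,
# dead (absorbing).

#' One annual Markov transition
#'
#' Death is evaluated against the status held at cycle start; the net quit
#' transition applies to current smokers surviving the cycle. Death is
#' absorbing.
#'
#' @param occupancy Numeric length-3 vector `(s_current, s_former, s_dead)`
#'   summing to 1.
#' @param p_death_current,p_death_former Annual death probabilities for the
#'   two alive states.
#' @param q_net Net annual current-to-former quit probability.
#' @return Named numeric length-3 occupancy after one cycle (sums to 1).
#' @examples
#' markov_step(c(1, 0, 0), 0.02, 0.015, 0.02)
#' @export
markov_step <- function(occupancy, p_death_current, p_death_former, q_net) {
  stopifnot(length(occupancy) == 3, abs(sum(occupancy) - 1) < 1e-9,
            p_death_current >= 0, p_death_current <= 1,
            p_death_former >= 0, p_death_former <= 1,
            q_net >= 0, q_net <= 1)
  sc <- occupancy[[1]]; sf <- occupancy[[2]]; sd <- occupancy[[3]]
  surv_c <- sc * (1 - p_death_current)
  c(s_current = surv_c * (1 - q_net),
    s_former = sf * (1 - p_death_former) + surv_c * q_net,
    s_dead = sd + sc * p_death_current + sf * p_death_former)
}

#' Run one age-sex cohort to age 100
#'
#' Simulates a cohort entering at `start_age` under one of two first-cycle
#' scenarios: `"quit_first_cycle"` starts the whole cohort as former smokers
#' (they carry former-smoker mortality and utility from cycle 1), while
#' `"no_quit_first_cycle"` starts it as current smokers. Each cycle the
#' cohort ages one year; status-specific mortality is looked up at the
#' attained age, and the net quit rate moves surviving current smokers to
#' the former-smoker state at cycle end, shaping occupancy from cycle 2
#' onward. The trace records state occupancy at the start of each cycle,
#' `T = 100 - start_age + 1` cycles in all.
#'
#' @param start_age Entry age (integer, `entry_age_min` to 100).
#' @param sex `"male"` or `"female"`.
#' @param scenario `"quit_first_cycle"` or `"no_quit_first_cycle"`.
#' @param dataset A [country_dataset()].
#' @param q_net Net quit probability; defaults to
#'   [net_quit_probability()] of the dataset settings.
#' @param sm Optional precomputed [status_mortality()] table (a performance
#'   hook for callers running many cohorts).
#' @return A `cohort_trace`: list with `occupancy` (T x 3 matrix), `age`
#'   (attained age per cycle), `final` (occupancy after the last cycle's
#'   transition), and the call metadata. Convert with
#'   `as.data.frame()`.
#' @export
run_cohort <- function(start_age, sex,
                       scenario = c("no_quit_first_cycle", "quit_first_cycle"),
                       dataset, q_net = NULL, sm = NULL) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(dataset, "country_dataset"))
  if (start_age > 100) roi_abort("start_age must be <= 100")
  if (start_age < dataset$settings$entry_age_min) {
    roi_abort("start_age below dataset entry age ",
              dataset$settings$entry_age_min)
  }
  if (is.null(q_net)) q_net <- net_quit_probability(dataset$settings)
  if (is.null(sm)) sm <- status_mortality(dataset)
  ages <- start_age:100L
  n <- length(ages)
  rows <- match(paste(sex, ages), paste(sm$sex, sm$age))
  if (anyNA(rows)) roi_abort("status mortality table does not cover ages ",
                             start_age, "-100 for sex '", sex, "'")
  p_c <- sm$p_current[rows]
  p_f <- sm$p_former[rows]

  occ <- matrix(0, nrow = n, ncol = 3,
                dimnames = list(NULL, c("s_current", "s_former", "s_dead")))
  occ[1, ] <- if (scenario == "quit_first_cycle") c(0, 1, 0) else c(1, 0, 0)
  sc <- occ[[1, 1]]; sf <- occ[[1, 2]]; sd <- occ[[1, 3]]
  for (t in seq_len(n)) {
    surv_c <- sc * (1 - p_c[t])
    sd <- sd + sc * p_c[t] + sf * p_f[t]
    sf <- sf * (1 - p_f[t]) + surv_c * q_net
    sc <- surv_c * (1 - q_net)
    if (t < n) occ[t + 1L, ] <- c(sc, sf, sd)
  }
  structure(
    list(start_age = as.integer(start_age), sex = sex, scenario = scenario,
         age = ages, occupancy = occ, final = c(s_current = sc,
                                                s_former = sf, s_dead = sd),
         q_net = q_net),
    class = "cohort_trace"
  )
}

#' @export
as.data.frame.cohort_trace <- function(x, ...) {
  data.frame(cycle = seq_along(x$age), age = x$age, x$occupancy)
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat("<cohort_trace> ", x$sex, " entering at age ", x$start_age,
      ", scenario ", x$scenario, "\n", sep = "")
  cat("  ", length(x$age), " annual cycles to age 100; final dead share ",
      format(x$final[["s_dead"]], digits = 4), "\n", sep = "")
  invisible(x)
}

#' Export a cohort trace to CSV
#'
#' Writes one row per cycle: `cycle, age, s_current, s_former, s_dead`.
#'
#' @param trace A `cohort_trace` from [run_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "cohort_trace"))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
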