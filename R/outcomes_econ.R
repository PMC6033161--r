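# Costs, life-years and QALYs from cohort traces: per-cycle accrual,
# discounting, horizon cuts and population weighting.

#' Expected utility decrement under the maximum-disutility comorbidity rule
#'
#' Disease occurrences are assumed independent; when several diseases are
#' present only the largest decrement applies. With diseases sorted by
#' decrement (descending) the expectation is
#' `sum_d dec_d * p_d * prod_{d' before d} (1 - p_d')`.
#'
#' @param prevalences Per-disease probabilities of having each disease.
#' @param decrements Per-disease utility decrements (same order).
#' @return Expected decrement (scalar).
#' @examples
#' expected_disease_decrement(c(0.1, 0.2), c(0.3, 0.1)) # 0.048
#' @export
expected_disease_decrement <- function(prevalences, decrements) {
  stopifnot(length(prevalences) == length(decrements))
  if (!length(prevalences)) return(0)
  o <- order(decrements, decreasing = TRUE)
  p <- prevalences[o]
  d <- decrements[o]
  none_before <- cumprod(c(1, 1 - p[-length(p)]))
  sum(d * p * none_before)
}

#' Annual utility for a smoking status at given disease prevalences
#'
#' Status utility minus the expected comorbidity decrement
#' ([expected_disease_decrement()]), floored at 0.
#'
#' @param status `"current"`, `"former"` or `"never"`.
#' @param utilities The `utilities` component of a [country_dataset()].
#' @param disease_prev Per-disease prevalences for this status and age, in
#'   the order of `utilities$decrements$disease`.
#' @return Utility per year.
#' @export
cycle_utility <- function(status = c("current", "former", "never"),
                          utilities, disease_prev) {
  status <- match.arg(status)
  u <- utilities[[paste0("u_", status)]]$value
  max(0, u - expected_disease_decrement(disease_prev,
                                        utilities$decrements$decrement))
}

#' Annual healthcare cost at given disease prevalences
#'
#' Costs are additive across diseases: `sum_d prev_d * annual_cost_d`.
#' Only alive states accrue cost.
#'
#' @param disease_prev Per-disease prevalences, in the order of
#'   `econ$disease`.
#' @param econ The `disease_costs` component of a [country_dataset()].
#' @return Currency per year.
#' @export
cycle_cost <- function(disease_prev, econ) {
  stopifnot(length(disease_prev) == nrow(econ))
  sum(disease_prev * econ$annual_cost)
}

#' Discount factor for an annual cycle
#'
#' Cycle 1 flows are taken at face value; cycle `t` is discounted by
#' `(1 + rate)^-(t - 1)`.
#'
#' @param rate Annual discount rate.
#' @param cycle Cycle index (integer `>= 1`), vectorised.
#' @return Discount factor(s).
#' @export
discount_factor <- function(rate, cycle) {
  stopifnot(rate >= 0, all(cycle >= 1))
  (1 + rate)^-(cycle - 1)
}

# Per-age annual cost and utility for the two alive statuses, for every
# age-sex cell of the dataset. One call per dataset (or per PSA draw).
cycle_values <- function(dataset) {
  sdp <- status_disease_prevalence(dataset)
  econ <- dataset$disease_costs
  ut <- dataset$utilities
  dec <- ut$decrements
  # align disease order across tables
  econ <- econ[match(roi_diseases, econ$disease), ]
  dec <- dec[match(roi_diseases, dec$disease), ]

  cells <- unique(sdp[, c("sex", "age")])
  key <- paste(sdp$sex, sdp$age)
  ckey <- paste(cells$sex, cells$age)
  prev_mat <- function(col) {
    m <- matrix(0, nrow = nrow(cells), ncol = length(roi_diseases))
    for (j in seq_along(roi_diseases)) {
      sub <- sdp[sdp$disease == roi_diseases[j], ]
      m[match(paste(sub$sex, sub$age), ckey), j] <- sub[[col]]
    }
    m
  }
  exp_dec <- function(m) {
    o <- order(dec$decrement, decreasing = TRUE)
    p <- m[, o, drop = FALSE]
    d <- dec$decrement[o]
    none <- rep(1, nrow(m))
    out <- numeric(nrow(m))
    for (j in seq_along(d)) {
      out <- out + d[j] * p[, j] * none
      none <- none * (1 - p[, j])
    }
    out
  }
  pc <- prev_mat("prev_current")
  pf <- prev_mat("prev_former")
  data.frame(
    sex = cells$sex, age = cells$age,
    cost_current = as.vector(pc %*% econ$annual_cost),
    cost_former = as.vector(pf %*% econ$annual_cost),
    util_current = pmax(0, ut$u_current$value - exp_dec(pc)),
    util_former = pmax(0, ut$u_former$value - exp_dec(pf))
  )
}

horizon_cycles <- function(horizon, n_cycles) {
  if (horizon == "lifetime") return(n_cycles)
  h <- as.integer(horizon)
  if (h > n_cycles) {
    warning("horizon ", horizon, " exceeds trace length ", n_cycles,
            "; truncated", call. = FALSE)
    return(n_cycles)
  }
  h
}

#' Accumulate costs, life-years and QALYs over a cohort trace
#'
#' Per cycle, expected cost and utility are occupancy-weighted over the two
#' alive states using status-specific disease prevalence at the attained
#' age; the life-year contribution is the alive share at cycle start; the
#' dead state accrues nothing. Cumulative sums are reported at each
#' configured horizon, discounted and undiscounted.
#'
#' @param trace A `cohort_trace` from [run_cohort()].
#' @param dataset The [country_dataset()] the trace was run against.
#' @param cv Optional precomputed per-age cost/utility table (internal
#'   performance hook).
#' @return A `person_outcomes` data frame with columns `horizon`,
#'   `discounted`, `cost`, `life_years`, `qalys`, `p_dead` (dead share at
#'   the end of the horizon), per average cohort member.
#' @export
accumulate_outcomes <- function(trace, dataset, cv = NULL) {
  stopifnot(inherits(trace, "cohort_trace"),
            inherits(dataset, "country_dataset"))
  if (is.null(cv)) cv <- cycle_values(dataset)
  rows <- match(paste(trace$sex, trace$age), paste(cv$sex, cv$age))
  occ <- trace$occupancy
  n <- nrow(occ)
  sc <- occ[, 1]; sf <- occ[, 2]
  cost_t <- sc * cv$cost_current[rows] + sf * cv$cost_former[rows]
  util_t <- sc * cv$util_current[rows] + sf * cv$util_former[rows]
  ly_t <- sc + sf
  dfac <- discount_factor(dataset$settings$discount_rate, seq_len(n))

  horizons <- dataset$settings$horizons
  dead_after <- c(occ[-1, 3], trace$final[["s_dead"]])
  out <- do.call(rbind, lapply(horizons, function(h) {
    k <- horizon_cycles(h, n)
    idx <- seq_len(k)
    data.frame(
      horizon = h,
      discounted = c(TRUE, FALSE),
      cost = c(sum(cost_t[idx] * dfac[idx]), sum(cost_t[idx])),
      life_years = c(sum(ly_t[idx] * dfac[idx]), sum(ly_t[idx])),
      qalys = c(sum(util_t[idx] * dfac[idx]), sum(util_t[idx])),
      p_dead = dead_after[k]
    )
  }))
  structure(out, class = c("person_outcomes", "data.frame"),
            scenario = trace$scenario, sex = trace$sex,
            start_age = trace$start_age)
}

#' Run both quit scenarios for every populated age-sex stratum
#'
#' For each stratum with smokers, runs the quit-first-cycle and
#' no-quit cohorts to age 100, accumulates outcomes, and weights the
#' per-stratum results into population averages via [weight_population()].
#'
#' @param dataset A [country_dataset()].
#' @param q_net Optional net quit probability override.
#' @return A `scenario_outcomes` list: `per_stratum` (data frame keyed by
#'   `sex`, `start_age`, `scenario`), `population` (weighted averages plus
#'   expected deaths), and `n_smokers` (total).
#' @export
run_scenarios <- function(dataset, q_net = NULL) {
  stopifnot(inherits(dataset, "country_dataset"))
  sm <- status_mortality(dataset)
  cv <- cycle_values(dataset)
  pop <- dataset$population
  pop <- pop[pop$n_smokers > 0, ]
  if (!nrow(pop)) roi_abort("no stratum with smokers to simulate")

  scen <- c("quit_first_cycle", "no_quit_first_cycle")
  pieces <- vector("list", nrow(pop) * 2L)
  k <- 0L
  for (i in seq_len(nrow(pop))) {
    for (s in scen) {
      tr <- run_cohort(pop$age[i], pop$sex[i], s, dataset,
                       q_net = q_net, sm = sm)
      po <- accumulate_outcomes(tr, dataset, cv = cv)
      k <- k + 1L
      pieces[[k]] <- cbind(
        data.frame(sex = pop$sex[i], start_age = pop$age[i], scenario = s),
        as.data.frame(po))
    }
  }
  per_stratum <- do.call(rbind, pieces)
  structure(
    list(per_stratum = per_stratum,
         population = weight_population(per_stratum, pop),
         n_smokers = sum(pop$n_smokers),
         settings = dataset$settings),
    class = "scenario_outcomes"
  )
}

#' Weight per-stratum outcomes into population averages
#'
#' Weighted arithmetic mean of per-stratum per-person outcomes, weights
#' proportional to the stratum smoker counts; expected deaths are
#' `sum n_smokers * p_dead` at each horizon.
#'
#' @param per_stratum Data frame of per-stratum outcomes with columns
#'   `sex`, `start_age`, `scenario`, `horizon`, `discounted`, `cost`,
#'   `life_years`, `qalys`, `p_dead`.
#' @param population Data frame `(sex, age, n_smokers)`.
#' @return A `population_outcomes` data frame with the per-person averages
#'   and a `deaths` column (expected cumulative deaths in persons).
#' @export
weight_population <- function(per_stratum, population) {
  w <- population$n_smokers[match(paste(per_stratum$sex, per_stratum$start_age),
                                  paste(population$sex, population$age))]
  if (anyNA(w)) roi_abort("population weights missing for some strata")
  if (sum(population$n_smokers) <= 0) roi_abort("total population is zero")
  groups <- split(seq_len(nrow(per_stratum)),
                  list(per_stratum$scenario, per_stratum$horizon,
                       per_stratum$discounted), drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(idx) {
    wi <- w[idx]
    data.frame(
      scenario = per_stratum$scenario[idx[1]],
      horizon = per_stratum$horizon[idx[1]],
      discounted = per_stratum$discounted[idx[1]],
      cost = sum(wi * per_stratum$cost[idx]) / sum(wi),
      life_years = sum(wi * per_stratum$life_years[idx]) / sum(wi),
      qalys = sum(wi * per_stratum$qalys[idx]) / sum(wi),
      p_dead = sum(wi * per_stratum$p_dead[idx]) / sum(wi),
      deaths = sum(wi * per_stratum$p_dead[idx])
    )
  }))
  rownames(out) <- NULL
  structure(out, class = c("population_outcomes", "data.frame"))
}

#' @export
print.scenario_outcomes <- function(x, ...) {
  cat("<scenario_outcomes> ", format(round(x$n_smokers)), " smokers, ",
      length(unique(paste(x$per_stratum$sex, x$per_stratum$start_age))),
      " strata\n", sep = "")
  print(as.data.frame(x$population), digits = 4)
  invisible(x)
}

#' Export scenario outcomes to CSV
#'
#' Writes per-stratum rows followed by population-weighted rows (the
#' latter flagged by `sex = "all"`, `start_age = NA`).
#'
#' @param outcomes A `scenario_outcomes` from [run_scenarios()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_outcomes <- function(outcomes, path) {
  stopifnot(inherits(outcomes, "scenario_outcomes"))
  popn <- as.data.frame(outcomes$population)
  popn <- cbind(data.frame(sex = "all", start_age = NA), popn)
  per <- outcomes$per_stratum
  per$deaths <- NA
  utils::write.csv(rbind(per, popn[, names(per)]), path, row.names = FALSE)
  invisible(path)
}
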