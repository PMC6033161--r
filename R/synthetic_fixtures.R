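# Synthetic country datasets (internally consistent, monotone-in-age) and
# the England per-smoker worked example.

#' Parameters for the synthetic country-dataset generator
#'
#' Shapes are chosen to look like a western European smoking population:
#' Gompertz-like mortality rising log-linearly with age, current-smoking
#' prevalence declining with age while former-smoking rises, and disease
#' prevalence zero before an onset age then saturating towards a plateau.
#'
#' @param seed Integer seed controlling the population-count jitter.
#' @param entry_age_min,entry_age_max Cohort entry age range (population
#'   counts are generated for entry ages; all other tables run to age 100).
#' @param mortality_p0 Baseline female annual death probability at the
#'   anchor age.
#' @param mortality_log_increase Annual log-increase in death probability
#'   (`g` in `p(a) = min(1, p0 * exp(g * (a - anchor)))`).
#' @param mortality_anchor_age Age at which `mortality_p0` applies (fixed at
#'   16 by default so that fixtures with different entry ages share the same
#'   mortality curve).
#' @param male_excess Multiplier on the female baseline for males.
#' @param current_start,current_decay Current-smoking prevalence at entry
#'   and its exponential decay rate with age.
#' @param former_base,former_max,former_rate Former-smoking prevalence:
#'   `former_base + former_max * (1 - exp(-former_rate * (a - entry_age)))`.
#' @param disease_onset,disease_plateau Named numeric vectors (one entry per
#'   disease in [roi_diseases]): first age with non-zero prevalence, and the
#'   saturation level approached at rate `disease_rise`.
#' @param disease_rise Saturation rate of disease prevalence past onset.
#' @param population_scale Expected smokers per entry-age stratum before
#'   jitter.
#' @param discount_rate,underlying_quit_rate,wtp_threshold,currency_code
#'   Passed to [analysis_settings()].
#' @return A list of class `fixture_params`.
#' @export
fixture_params <- function(seed = 1,
                           entry_age_min = 16, entry_age_max = 85,
                           mortality_p0 = 2e-4,
                           mortality_log_increase = 0.085,
                           mortality_anchor_age = 16,
                           male_excess = 1.2,
                           current_start = 0.25, current_decay = 0.012,
                           former_base = 0.08, former_max = 0.30,
                           former_rate = 0.03,
                           disease_onset = c(lung_cancer = 40, chd = 35,
                                             copd = 40, stroke = 45),
                           disease_plateau = c(lung_cancer = 0.010,
                                               chd = 0.120, copd = 0.080,
                                               stroke = 0.060),
                           disease_rise = 0.05,
                           population_scale = 1000,
                           discount_rate = 0.035,
                           underlying_quit_rate = 0.02,
                           wtp_threshold = 20000,
                           currency_code = "GBP") {
  stopifnot(entry_age_min >= 16, entry_age_max <= 85,
            entry_age_min <= entry_age_max)
  if (mortality_p0 <= 0 || mortality_p0 > 1) {
    roi_abort("mortality_p0 must be a probability in (0, 1]")
  }
  if (current_start < 0 || current_start > 1 ||
      former_base + former_max + current_start > 1) {
    roi_abort("smoking prevalence curve parameters must keep proportions in [0, 1]")
  }
  if (any(disease_plateau < 0 | disease_plateau > 1)) {
    roi_abort("disease_plateau values must be probabilities")
  }
  structure(as.list(environment()), class = "fixture_params")
}

#' Generate a synthetic country dataset
#'
#' Produces a complete, internally consistent [country_dataset()]
#' deterministically from [fixture_params()]: every generated table passes
#' the full validation suite and round-trips through
#' [write_country_dataset()] / [load_country_dataset()].
#'
#' @param params A [fixture_params()] list.
#' @return A validated `country_dataset`.
#' @examples
#' ds <- generate_country_dataset(fixture_params(seed = 7))
#' @export
generate_country_dataset <- function(params = fixture_params()) {
  stopifnot(inherits(params, "fixture_params"))
  p <- params
  ages <- p$entry_age_min:100L

  grid <- expand.grid(sex = roi_sexes, age = ages,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$sex, grid$age), ]
  rel_g <- grid$age - p$entry_age_min
  p0 <- ifelse(grid$sex == "male", p$mortality_p0 * p$male_excess,
               p$mortality_p0)
  life_table <- data.frame(
    sex = grid$sex, age = grid$age,
    p_death = pmin(1, p0 * exp(p$mortality_log_increase *
                                 (grid$age - p$mortality_anchor_age)))
  )

  pi_current <- p$current_start * exp(-p$current_decay * rel_g)
  pi_former <- p$former_base +
    p$former_max * (1 - exp(-p$former_rate * rel_g))
  smoking_prevalence <- data.frame(
    sex = grid$sex, age = grid$age,
    pi_never = 1 - pi_current - pi_former,
    pi_former = pi_former, pi_current = pi_current
  )

  disease_prevalence <- do.call(rbind, lapply(roi_diseases, function(d) {
    past <- pmax(0, grid$age - p$disease_onset[[d]])
    data.frame(disease = d, sex = grid$sex, age = grid$age,
               prev_all = ifelse(past > 0,
                                 p$disease_plateau[[d]] *
                                   (1 - exp(-p$disease_rise * past)), 0))
  }))

  mortality_rr <- list(rr_current = list(value = 2.0, se = 0.05),
                       rr_former = list(value = 1.3, se = 0.05))
  disease_rr <- data.frame(
    disease = roi_diseases,
    rr_current = c(10, 2.0, 6, 1.8),
    rr_current_se = c(0.10, 0.08, 0.10, 0.08),
    rr_former = c(4, 1.4, 3, 1.3),
    rr_former_se = c(0.10, 0.08, 0.10, 0.08)
  )
  disease_costs <- data.frame(
    disease = roi_diseases,
    annual_cost = c(12000, 3000, 2500, 8000),
    se = c(1500, 400, 350, 1000)
  )
  utilities <- list(
    u_current = list(value = 0.85, se = 0.01),
    u_former = list(value = 0.88, se = 0.01),
    u_never = list(value = 0.91, se = 0.01),
    decrements = data.frame(
      disease = roi_diseases,
      decrement = c(0.15, 0.06, 0.10, 0.12),
      se = c(0.02, 0.01, 0.015, 0.02)
    )
  )

  entry_ages <- p$entry_age_min:p$entry_age_max
  pgrid <- expand.grid(sex = roi_sexes, age = entry_ages,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pgrid <- pgrid[order(pgrid$sex, pgrid$age), ]
  shape <- exp(-((pgrid$age - 35) / 22)^2)  # smokers concentrated 25-50
  counts <- local({
    old <- .Random.seed_exists()
    on.exit(restore_seed(old), add = TRUE)
    set.seed(params$seed)
    round(p$population_scale * shape * stats::rlnorm(nrow(pgrid), 0, 0.1))
  })
  population <- data.frame(sex = pgrid$sex, age = pgrid$age,
                           n_smokers = as.integer(pmax(counts, 1)))

  country_dataset(
    life_table = life_table,
    smoking_prevalence = smoking_prevalence,
    disease_prevalence = disease_prevalence,
    mortality_rr = mortality_rr,
    disease_rr = disease_rr,
    disease_costs = disease_costs,
    utilities = utilities,
    population = population,
    settings = analysis_settings(
      discount_rate = p$discount_rate,
      underlying_quit_rate = p$underlying_quit_rate,
      wtp_threshold = p$wtp_threshold,
      currency_code = p$currency_code,
      entry_age_min = p$entry_age_min
    )
  )
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' England per-smoker worked example
#'
#' Published per-smoker lifetime discounted outcomes for an average English
#' smoker under the two scenarios — quit within the next 12 months (cost
#' 9602, 15.86 QALYs, 19.11 life-years) versus continue (cost 14563, 14.77
#' QALYs, 18.45 life-years) — together with the illustrative intervention
#' packages they are conventionally combined with: a status quo (20% make a
#' quit attempt, 5% unaided success), a population-level campaign raising
#' the attempt rate by a relative 25% for a fixed 40000, a novel cessation
#' aid (uptake 20% of attempters, success RR 1.25, 225 per attempt), and a
#' promotion drive doubling that uptake for a further fixed 50000.
#'
#' These per-smoker values feed [evaluate_package()] directly, bypassing
#' the Markov engine, so the package-comparison arithmetic can be exercised
#' without the underlying national datasets.
#'
#' @return A list: `outcomes` (`quit` / `no_quit` per-smoker lifetime
#'   discounted values), `packages` (named list of [package_spec()]s),
#'   `n_smokers` (2000), `threshold` (20000), `currency` ("GBP").
#' @export
england_worked_example <- function() {
  list(
    outcomes = list(
      quit = list(cost = 9602, qalys = 15.86, life_years = 19.11),
      no_quit = list(cost = 14563, qalys = 14.77, life_years = 18.45)
    ),
    packages = list(
      status_quo = package_spec(
        "status quo", baseline_attempt_rate = 0.20, unaided_success = 0.05),
      attempt_boost = package_spec(
        "attempt-rate campaign",
        interventions = list(intervention("media campaign", uptake = 0,
                                          attempt_rate_multiplier = 1.25,
                                          fixed_cost = 40000)),
        baseline_attempt_rate = 0.20, unaided_success = 0.05),
      novel_aid = package_spec(
        "novel cessation aid",
        interventions = list(intervention("novel aid", uptake = 0.20,
                                          rr_success = 1.25,
                                          cost_per_use = 225)),
        baseline_attempt_rate = 0.20, unaided_success = 0.05),
      novel_aid_promoted = package_spec(
        "novel aid + uptake drive",
        interventions = list(
          intervention("novel aid", uptake = 0.40, rr_success = 1.25,
                       cost_per_use = 225),
          intervention("uptake drive", uptake = 0, fixed_cost = 50000)),
        baseline_attempt_rate = 0.20, unaided_success = 0.05)
    ),
    n_smokers = 2000,
    threshold = 20000,
    currency = "GBP"
  )
}

#' Run the three illustrative package comparisons
#'
#' Evaluates the worked-example packages on the published per-smoker
#' outcomes and returns the three standard comparisons: the attempt-rate
#' campaign and the novel aid each against the status quo, and the
#' promoted novel aid against the plain novel aid.
#'
#' @param we A worked-example bundle from [england_worked_example()].
#' @return Named list of three `roi_comparison` objects
#'   (`attempt_boost`, `novel_aid`, `novel_aid_promoted`).
#' @examples
#' comps <- worked_example_comparisons()
#' comps$attempt_boost$icer_rounded # 2788
#' @export
worked_example_comparisons <- function(we = england_worked_example()) {
  res <- lapply(we$packages, evaluate_package, outcomes = we$outcomes,
                n_smokers = we$n_smokers)
  list(
    attempt_boost = compare_packages(res$status_quo, res$attempt_boost,
                                     threshold = we$threshold),
    novel_aid = compare_packages(res$status_quo, res$novel_aid,
                                 threshold = we$threshold),
    novel_aid_promoted = compare_packages(res$novel_aid,
                                          res$novel_aid_promoted,
                                          threshold = we$threshold)
  )
}
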