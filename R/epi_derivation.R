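# Decomposition of population-level mortality and disease prevalence into
# smoking-status-specific values, and first-cycle / ongoing quit
# probabilities.

# Age below which disease risk is assumed equal across smoking statuses:
# differential rates are not observed in the young and absolute prevalence
# there is very low.
EQUAL_RISK_AGE <- 35

cap_probability <- function(p, what) {
  if (any(p > 1)) {
    warning(what, ": probability exceeded 1 after relative-risk scaling; capped",
            call. = FALSE)
    p <- pmin(p, 1)
  }
  p
}

#' Split a population death probability by smoking status
#'
#' Solves the one-unknown linear decomposition: the never-smoker probability
#' is `p_all / (pi_never + pi_former * rr_former + pi_current * rr_current)`
#' and the former/current values scale it by their relative risks, so the
#' status-prevalence-weighted mean of the outputs reproduces `p_all`
#' exactly (before capping at 1). Vectorised over `p_all` and the
#' prevalence columns.
#'
#' @param p_all Annual probability of death in the general population.
#' @param pi_never,pi_former,pi_current Smoking-status proportions, summing
#'   to 1.
#' @param rr_former,rr_current Relative risks of death versus never smokers.
#' @return Data frame with columns `p_never`, `p_former`, `p_current`,
#'   each capped at 1.
#' @examples
#' mortality_by_status(0.02, 0.5, 0.2, 0.3, rr_former = 1.3, rr_current = 2)
#' @export
mortality_by_status <- function(p_all, pi_never, pi_former, pi_current,
                                rr_former, rr_current) {
  denom <- pi_never + pi_former * rr_former + pi_current * rr_current
  if (any(denom <= 0)) {
    roi_abort("mortality_by_status: zero denominator (all status proportions zero)")
  }
  p_never <- p_all / denom
  data.frame(
    p_never = cap_probability(p_never, "p_never"),
    p_former = cap_probability(rr_former * p_never, "p_former"),
    p_current = cap_probability(rr_current * p_never, "p_current")
  )
}

#' Split a population disease prevalence by smoking status
#'
#' Applies the same linear decomposition as [mortality_by_status()], with
#' one exception: below age 35 the risk of smoking-attributable disease is
#' taken as equal across smoking groups, so all three outputs equal
#' `prev_all` there. Relative effects are interpreted as prevalence ratios.
#' Vectorised over ages and prevalences.
#'
#' @param prev_all Overall disease prevalence.
#' @param pi_never,pi_former,pi_current Smoking-status proportions.
#' @param rr_former,rr_current Prevalence ratios versus never smokers.
#' @param age Attained age in years (scalar or vector).
#' @return Data frame with columns `prev_never`, `prev_former`,
#'   `prev_current`, capped at 1.
#' @export
disease_prevalence_by_status <- function(prev_all, pi_never, pi_former,
                                         pi_current, rr_former, rr_current,
                                         age) {
  young <- age < EQUAL_RISK_AGE
  rr_former <- ifelse(young, 1, rr_former)
  rr_current <- ifelse(young, 1, rr_current)
  out <- mortality_by_status(prev_all, pi_never, pi_former, pi_current,
                             rr_former, rr_current)
  names(out) <- c("prev_never", "prev_former", "prev_current")
  out
}

#' Status-specific mortality table for a dataset
#'
#' Joins the life table with smoking prevalence and applies
#' [mortality_by_status()] at every age-sex cell. Mortality relative risks
#' apply at all ages (the under-35 equal-risk rule concerns disease only).
#'
#' @param dataset A [country_dataset()].
#' @return Data frame `(sex, age, p_never, p_former, p_current)`.
#' @export
status_mortality <- function(dataset) {
  stopifnot(inherits(dataset, "country_dataset"))
  lt <- dataset$life_table
  sp <- dataset$smoking_prevalence
  m <- merge(lt, sp, by = c("sex", "age"), sort = FALSE)
  m <- m[order(m$sex, m$age), ]
  out <- mortality_by_status(m$p_death, m$pi_never, m$pi_former, m$pi_current,
                             rr_former = dataset$mortality_rr$rr_former$value,
                             rr_current = dataset$mortality_rr$rr_current$value)
  cbind(m[, c("sex", "age")], out)
}

#' Status-specific disease prevalence table for a dataset
#'
#' @param dataset A [country_dataset()].
#' @return Data frame
#'   `(disease, sex, age, prev_never, prev_former, prev_current)`.
#' @export
status_disease_prevalence <- function(dataset) {
  stopifnot(inherits(dataset, "country_dataset"))
  sp <- dataset$smoking_prevalence
  out <- lapply(roi_diseases, function(d) {
    dp <- dataset$disease_prevalence
    dp <- dp[dp$disease == d, ]
    m <- merge(dp, sp, by = c("sex", "age"), sort = FALSE)
    m <- m[order(m$sex, m$age), ]
    rr <- dataset$disease_rr[dataset$disease_rr$disease == d, ]
    res <- disease_prevalence_by_status(
      m$prev_all, m$pi_never, m$pi_former, m$pi_current,
      rr_former = rr$rr_former, rr_current = rr$rr_current, age = m$age)
    cbind(data.frame(disease = d), m[, c("sex", "age")], res)
  })
  do.call(rbind, out)
}

#' First-cycle quit probability of a package
#'
#' The probability that a current smoker quits during the first model year:
#' the effective attempt rate times the blended success probability across
#' intervention users and unaided attempters,
#' `A_eff * (sum_i uptake_i * rr_success_i * s0 + (1 - sum_i uptake_i) * s0)`
#' with `s0` the unaided success probability.
#'
#' @param package A [package_spec()].
#' @return Probability in `[0, 1]`.
#' @examples
#' sq <- package_spec("status quo", baseline_attempt_rate = 0.2,
#'                    unaided_success = 0.05)
#' first_cycle_quit_probability(sq) # 0.01
#' @export
first_cycle_quit_probability <- function(package) {
  stopifnot(inherits(package, "package_spec"))
  a_eff <- effective_attempt_rate(package)
  s0 <- package$unaided_success
  uptakes <- vapply(package$interventions, `[[`, numeric(1), "uptake")
  rrs <- vapply(package$interventions, `[[`, numeric(1), "rr_success")
  succ <- rrs * s0
  bad <- which(succ > 1)
  if (length(bad)) {
    roi_abort("package '", package$name, "': intervention '",
              package$interventions[[bad[1]]]$name,
              "' implies per-attempt success ", format(succ[bad[1]]), " > 1")
  }
  blended <- sum(uptakes * succ) + (1 - sum(uptakes)) * s0
  q <- a_eff * blended
  stopifnot(q >= 0, q <= 1)
  q
}

#' Ongoing net quit probability
#'
#' The annual net current-to-former transition probability applied from the
#' second cycle onward. It is a net rate balancing cessation against relapse
#' and initiation, configured per country (about 0.02 for most western
#' European smoking populations, 0.01 for Hungary) and constant in age.
#'
#' @param settings An [analysis_settings()] object (or a `country_dataset`,
#'   whose settings are used).
#' @return Probability in `[0, 1]`.
#' @export
net_quit_probability <- function(settings) {
  if (inherits(settings, "country_dataset")) settings <- settings$settings
  stopifnot(inherits(settings, "roi_settings"))
  settings$underlying_quit_rate
}
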