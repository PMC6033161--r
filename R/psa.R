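# Probabilistic sensitivity analysis: distribution assignment by parameter
# class, Monte Carlo replication of the whole pipeline, scatter and CEAC
# outputs.

#' Assign uncertainty distributions to a dataset's parameters
#'
#' Follows the standard class rules for decision models: probabilities and
#' status utilities get beta distributions, relative risks lognormal (the
#' stored standard error is on the log scale), disease costs gamma, utility
#' decrements normal; intervention costs and population-level data (life
#' table, prevalences, smoker counts, discount rate, net quit rate) stay
#' fixed. Beta and gamma are parameterised by method of moments from
#' `(point_estimate, standard_error)`.
#'
#' A stochastic parameter with standard error 0 degenerates to fixed with a
#' warning; a standard error too large for the beta support raises an error.
#'
#' @param dataset A [country_dataset()].
#' @return A `parameter_distributions` data frame with columns `id`,
#'   `family` (`beta`, `lognormal`, `gamma`, `normal` or `fixed`), `mean`
#'   and `se`, ordered by `id`.
#' @export
assign_distributions <- function(dataset) {
  stopifnot(inherits(dataset, "country_dataset"))
  rr <- dataset$mortality_rr
  drr <- dataset$disease_rr
  ut <- dataset$utilities
  rows <- list(
    data.frame(id = "rr_death_current", family = "lognormal",
               mean = rr$rr_current$value, se = rr$rr_current$se %||% 0),
    data.frame(id = "rr_death_former", family = "lognormal",
               mean = rr$rr_former$value, se = rr$rr_former$se %||% 0),
    data.frame(id = paste0("rr_", drr$disease, "_current"),
               family = "lognormal", mean = drr$rr_current,
               se = drr$rr_current_se),
    data.frame(id = paste0("rr_", drr$disease, "_former"),
               family = "lognormal", mean = drr$rr_former,
               se = drr$rr_former_se),
    data.frame(id = paste0("cost_", dataset$disease_costs$disease),
               family = "gamma", mean = dataset$disease_costs$annual_cost,
               se = dataset$disease_costs$se),
    data.frame(id = c("u_current", "u_former", "u_never"), family = "beta",
               mean = c(ut$u_current$value, ut$u_former$value,
                        ut$u_never$value),
               se = c(ut$u_current$se %||% 0, ut$u_former$se %||% 0,
                      ut$u_never$se %||% 0)),
    data.frame(id = paste0("decrement_", ut$decrements$disease),
               family = "normal", mean = ut$decrements$decrement,
               se = ut$decrements$se)
  )
  d <- do.call(rbind, rows)
  d <- d[order(d$id), ]
  rownames(d) <- NULL

  degenerate <- d$family != "fixed" & (is.na(d$se) | d$se == 0)
  if (any(degenerate)) {
    warning("parameters with zero standard error treated as fixed: ",
            paste(d$id[degenerate], collapse = ", "), call. = FALSE)
    d$family[degenerate] <- "fixed"
    d$se[degenerate] <- 0
  }
  beta <- d$family == "beta"
  infeasible <- beta & (d$mean <= 0 | d$mean >= 1 |
                          d$se^2 >= d$mean * (1 - d$mean))
  if (any(infeasible)) {
    roi_abort("beta moment-matching infeasible (se too large for support): ",
              paste(d$id[infeasible], collapse = ", "))
  }
  structure(d, class = c("parameter_distributions", "data.frame"))
}

#' Draw parameter values from their assigned distributions
#'
#' Draws use the current RNG state, one column per parameter in the (sorted)
#' order of `dists$id`. Beta uses `alpha = m * nu`, `beta = (1 - m) * nu`
#' with `nu = m (1 - m) / s^2 - 1`; gamma uses `shape = (m / s)^2`,
#' `rate = m / s^2`; lognormal uses `meanlog = log(m)`, `sdlog = s`;
#' normal uses `(m, s)`. Fixed parameters repeat their point estimate.
#'
#' @param dists A `parameter_distributions` data frame from
#'   [assign_distributions()].
#' @param n Number of draws.
#' @return An `n` x `nrow(dists)` numeric matrix with parameter ids as
#'   column names.
#' @export
sample_parameters <- function(dists, n = 1) {
  stopifnot(inherits(dists, "parameter_distributions"), n >= 1)
  out <- matrix(NA_real_, nrow = n, ncol = nrow(dists),
                dimnames = list(NULL, dists$id))
  for (j in seq_len(nrow(dists))) {
    m <- dists$mean[j]; s <- dists$se[j]
    out[, j] <- switch(
      dists$family[j],
      fixed = rep(m, n),
      beta = {
        nu <- m * (1 - m) / s^2 - 1
        stats::rbeta(n, m * nu, (1 - m) * nu)
      },
      gamma = stats::rgamma(n, shape = (m / s)^2, rate = m / s^2),
      lognormal = stats::rlnorm(n, meanlog = log(m), sdlog = s),
      normal = stats::rnorm(n, m, s),
      roi_abort("unknown distribution family: ", dists$family[j])
    )
  }
  out
}

# Substitute one row of parameter draws back into a dataset.
apply_parameter_draws <- function(dataset, draws) {
  if (!length(draws)) return(dataset)
  get1 <- function(id, default) {
    if (id %in% names(draws)) draws[[id]] else default
  }
  ds <- dataset
  ds$mortality_rr$rr_current$value <-
    get1("rr_death_current", ds$mortality_rr$rr_current$value)
  ds$mortality_rr$rr_former$value <-
    get1("rr_death_former", ds$mortality_rr$rr_former$value)
  for (i in seq_len(nrow(ds$disease_rr))) {
    d <- ds$disease_rr$disease[i]
    ds$disease_rr$rr_current[i] <-
      get1(paste0("rr_", d, "_current"), ds$disease_rr$rr_current[i])
    ds$disease_rr$rr_former[i] <-
      get1(paste0("rr_", d, "_former"), ds$disease_rr$rr_former[i])
  }
  for (i in seq_len(nrow(ds$disease_costs))) {
    d <- ds$disease_costs$disease[i]
    ds$disease_costs$annual_cost[i] <-
      get1(paste0("cost_", d), ds$disease_costs$annual_cost[i])
  }
  for (nm in c("u_current", "u_former", "u_never")) {
    ds$utilities[[nm]]$value <- get1(nm, ds$utilities[[nm]]$value)
  }
  for (i in seq_len(nrow(ds$utilities$decrements))) {
    d <- ds$utilities$decrements$disease[i]
    ds$utilities$decrements$decrement[i] <-
      pmax(0, get1(paste0("decrement_", d),
                   ds$utilities$decrements$decrement[i]))
  }
  ds
}

#' Run a probabilistic sensitivity analysis
#'
#' Re-runs the full pipeline (status-specific derivation, Markov cohorts,
#' outcome accumulation, population weighting, package evaluation) once per
#' replicate with parameters drawn from [assign_distributions()], and
#' records incremental costs and QALYs of each package against the
#' comparator (the first package).
#'
#' Reproducibility: the master `seed` generates one sub-seed per replicate;
#' each replicate seeds its own stream and draws all parameters in sorted-id
#' order, so results do not depend on evaluation order and are identical for
#' identical `(seed, n_reps)`.
#'
#' @param dataset A [country_dataset()].
#' @param packages List of two or more [package_spec()]s; the first is the
#'   comparator.
#' @param n_reps Number of Monte Carlo replications (default 1000).
#' @param seed Master integer seed.
#' @param horizon,discounted Outcome slice compared (default lifetime,
#'   discounted).
#' @return A `psa_replicates` data frame `(rep, comparison, delta_cost,
#'   delta_qalys)` with attributes `seed`, `n_reps`, `horizon`,
#'   `threshold` (from the dataset settings) and `comparator`.
#' @seealso [ceac()], [export_scatter()]
#' @export
run_psa <- function(dataset, packages, n_reps = 1000, seed = 1,
                    horizon = "lifetime", discounted = TRUE) {
  stopifnot(inherits(dataset, "country_dataset"), n_reps >= 1)
  if (length(packages) < 2) {
    roi_abort("run_psa needs a comparator plus at least one package")
  }
  names(packages) <- vapply(packages, `[[`, character(1), "name")
  dists <- suppressWarnings(assign_distributions(dataset))
  active <- dists[dists$family != "fixed", , drop = FALSE]

  old <- .Random.seed_exists()
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)

  others <- packages[-1]
  pieces <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    ds_r <- if (nrow(active)) {
      set.seed(rep_seeds[r])
      apply_parameter_draws(dataset, drop(sample_parameters(active, 1)))
    } else dataset
    out_r <- run_scenarios(ds_r)
    base <- evaluate_package(packages[[1]], out_r, horizon = horizon,
                             discounted = discounted)
    pieces[[r]] <- do.call(rbind, lapply(names(others), function(nm) {
      res <- evaluate_package(others[[nm]], out_r, horizon = horizon,
                              discounted = discounted)
      data.frame(rep = r,
                 comparison = paste(nm, "vs", packages[[1]]$name),
                 delta_cost = res$expected_cost - base$expected_cost,
                 delta_qalys = res$expected_qalys - base$expected_qalys)
    }))
  }
  structure(do.call(rbind, pieces),
            class = c("psa_replicates", "data.frame"),
            seed = seed, n_reps = n_reps, horizon = horizon,
            discounted = discounted,
            threshold = dataset$settings$wtp_threshold,
            comparator = packages[[1]]$name)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold, the fraction of PSA replicates
#' whose net monetary benefit `threshold * delta_qalys - delta_cost` is
#' strictly positive (ties count as not cost-effective).
#'
#' @param reps A `psa_replicates` data frame from [run_psa()], or any data
#'   frame with `comparison`, `delta_cost`, `delta_qalys`.
#' @param thresholds Non-empty numeric vector of thresholds; default a
#'   0 to 50000 grid in steps of 1000.
#' @return A `ceac_curve` data frame
#'   `(comparison, threshold, prob_cost_effective)`.
#' @export
ceac <- function(reps, thresholds = seq(0, 50000, by = 1000)) {
  stopifnot(length(thresholds) >= 1)
  out <- do.call(rbind, lapply(split(reps, reps$comparison), function(g) {
    data.frame(
      comparison = g$comparison[1],
      threshold = thresholds,
      prob_cost_effective = vapply(thresholds, function(l) {
        mean(l * g$delta_qalys - g$delta_cost > 0)
      }, numeric(1))
    )
  }))
  rownames(out) <- NULL
  structure(out, class = c("ceac_curve", "data.frame"))
}

#' Incremental cost-QALY scatter data
#'
#' One row per replicate and comparison (`delta_qalys`, `delta_cost`),
#' with per-comparison means attached as the `"summary"` attribute — the
#' data behind the conventional cost-effectiveness plane scatterplot.
#'
#' @param reps A `psa_replicates` data frame from [run_psa()].
#' @return A data frame `(rep, comparison, delta_qalys, delta_cost)`.
#' @export
export_scatter <- function(reps) {
  stopifnot(nrow(reps) >= 1)
  out <- data.frame(rep = reps$rep, comparison = reps$comparison,
                    delta_qalys = reps$delta_qalys,
                    delta_cost = reps$delta_cost)
  means <- do.call(rbind, lapply(split(out, out$comparison), function(g) {
    data.frame(comparison = g$comparison[1],
               mean_delta_qalys = mean(g$delta_qalys),
               mean_delta_cost = mean(g$delta_cost))
  }))
  rownames(means) <- NULL
  attr(out, "summary") <- means
  out
}
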