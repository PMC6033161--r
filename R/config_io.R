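# Domain data model, file input/output and validation for country datasets
# and intervention-package specifications.

#' Diseases tracked by the model
#'
#' The four smoking-attributable diseases carried through every stage of the
#' model: lung cancer, coronary heart disease (CHD), chronic obstructive
#' pulmonary disease (COPD) and stroke.
#'
#' @format Character vector of length 4.
#' @export
roi_diseases <- c("lung_cancer", "chd", "copd", "stroke")

roi_sexes <- c("male", "female")

roi_abort <- function(...) stop(paste0(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

check_numeric_range <- function(x, what, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || anyNA(x)) {
    roi_abort(what, " must be numeric and non-missing")
  }
  bad <- which(x < lo | x > hi)
  if (length(bad)) {
    roi_abort(what, " out of range [", lo, ", ", hi, "] at position ",
              bad[1], " (value ", format(x[bad[1]]), ")")
  }
  invisible(x)
}

#' Analysis settings
#'
#' Run-level settings shared by the deterministic and probabilistic analyses.
#'
#' @param discount_rate Annual discount rate applied to costs and outcomes
#'   from the second cycle onward (dimensionless, `>= 0`).
#' @param underlying_quit_rate Annual net probability that a current smoker
#'   becomes a former smoker from the second cycle onward. This is a *net*
#'   rate balancing cessation against relapse and initiation; around 0.02 is
#'   typical for western European smoking populations, 0.01 for Hungary.
#' @param horizons Character vector, a non-empty subset of
#'   `c("2", "5", "10", "lifetime")`. `"lifetime"` runs the cohort to age 100.
#' @param wtp_threshold Willingness to pay for one QALY, in currency units.
#' @param currency_code Currency label; carried through unchanged, never
#'   converted.
#' @param entry_age_min Youngest cohort entry age (16 typical; 18 for
#'   countries whose smoking surveys start at 18).
#' @return A list of class `roi_settings`.
#' @export
analysis_settings <- function(discount_rate = 0.035,
                              underlying_quit_rate = 0.02,
                              horizons = c("2", "5", "10", "lifetime"),
                              wtp_threshold = 20000,
                              currency_code = "GBP",
                              entry_age_min = 16) {
  horizons <- as.character(horizons)
  allowed <- c("2", "5", "10", "lifetime")
  if (length(horizons) == 0L || !all(horizons %in% allowed)) {
    roi_abort("horizons must be a non-empty subset of {",
              paste(allowed, collapse = ", "), "}")
  }
  check_numeric_range(discount_rate, "discount_rate", 0)
  check_numeric_range(underlying_quit_rate, "underlying_quit_rate", 0, 1)
  check_numeric_range(wtp_threshold, "wtp_threshold", 0)
  if (entry_age_min < 16 || entry_age_min > 85) {
    roi_abort("entry_age_min must lie in [16, 85]")
  }
  structure(
    list(discount_rate = discount_rate,
         underlying_quit_rate = underlying_quit_rate,
         horizons = horizons,
         wtp_threshold = wtp_threshold,
         currency_code = currency_code,
         entry_age_min = as.integer(entry_age_min)),
    class = "roi_settings"
  )
}

#' Assemble a country dataset
#'
#' Bundles all epidemiological and economic inputs for one country into a
#' single validated object. Most users will call [load_country_dataset()] on
#' a dataset directory or [generate_country_dataset()] for a synthetic one
#' rather than this constructor directly.
#'
#' @param life_table Data frame `(sex, age, p_death)`: annual probability of
#'   death in the general population, every integer age from the entry age
#'   to 100, both sexes.
#' @param smoking_prevalence Data frame
#'   `(sex, age, pi_never, pi_former, pi_current)`; the three proportions
#'   must sum to 1 (tolerance 1e-9) in every row.
#' @param disease_prevalence Data frame `(disease, sex, age, prev_all)`
#'   covering all four diseases in [roi_diseases].
#' @param mortality_rr List with elements `rr_current` and `rr_former`, each
#'   `list(value, se)`: relative risk of death versus never smokers. `se` is
#'   the standard error of the *log* relative risk.
#' @param disease_rr Data frame
#'   `(disease, rr_current, rr_current_se, rr_former, rr_former_se)`:
#'   relative effect of smoking status on disease prevalence (`se` again on
#'   the log scale).
#' @param disease_costs Data frame `(disease, annual_cost, se)`: annual
#'   healthcare cost per prevalent case.
#' @param utilities List with `u_current`, `u_former`, `u_never` (each
#'   `list(value, se)`) and `decrements`, a data frame
#'   `(disease, decrement, se)` of utility decrements.
#' @param population Data frame `(sex, age, n_smokers)`: current smokers per
#'   age-sex stratum, used as cohort weights.
#' @param settings An [analysis_settings()] object.
#' @return A validated list of class `country_dataset`.
#' @seealso [load_country_dataset()], [write_country_dataset()],
#'   [generate_country_dataset()]
#' @export
country_dataset <- function(life_table, smoking_prevalence,
                            disease_prevalence, mortality_rr, disease_rr,
                            disease_costs, utilities, population, settings) {
  x <- structure(
    list(life_table = as.data.frame(life_table),
         smoking_prevalence = as.data.frame(smoking_prevalence),
         disease_prevalence = as.data.frame(disease_prevalence),
         mortality_rr = mortality_rr,
         disease_rr = as.data.frame(disease_rr),
         disease_costs = as.data.frame(disease_costs),
         utilities = utilities,
         population = as.data.frame(population),
         settings = settings),
    class = "country_dataset"
  )
  validate_country_dataset(x)
}

check_cols <- function(df, cols, file) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    roi_abort(file, ": missing column(s) ", paste(miss, collapse = ", "))
  }
}

check_age_sex_coverage <- function(df, ages, file) {
  for (s in roi_sexes) {
    have <- sort(unique(df$age[df$sex == s]))
    miss <- setdiff(ages, have)
    if (length(miss)) {
      roi_abort(file, ": sex '", s, "' missing age(s) ",
                paste(utils::head(miss, 5), collapse = ", "),
                if (length(miss) > 5) ", ..." else "")
    }
    if (anyDuplicated(df$age[df$sex == s])) {
      roi_abort(file, ": duplicated age rows for sex '", s, "'")
    }
  }
}

#' Validate a country dataset
#'
#' Checks ranges, row sums, age-sex coverage and cross-component alignment.
#' Violations raise errors naming the offending table, row and field;
#' implausible-but-legal orderings (e.g. `rr_former > rr_current`) only warn.
#'
#' @param x A `country_dataset`.
#' @return `x`, invisibly unchanged, if valid.
#' @export
validate_country_dataset <- function(x) {
  stopifnot(inherits(x, "country_dataset"))
  st <- x$settings
  ages <- st$entry_age_min:100L

  lt <- x$life_table
  check_cols(lt, c("sex", "age", "p_death"), "life_table")
  check_age_sex_coverage(lt, ages, "life_table")
  check_numeric_range(lt$p_death, "life_table$p_death", 0, 1)

  sp <- x$smoking_prevalence
  check_cols(sp, c("sex", "age", "pi_never", "pi_former", "pi_current"),
             "smoking_prevalence")
  check_age_sex_coverage(sp, ages, "smoking_prevalence")
  for (col in c("pi_never", "pi_former", "pi_current")) {
    check_numeric_range(sp[[col]], paste0("smoking_prevalence$", col), 0, 1)
  }
  sums <- sp$pi_never + sp$pi_former + sp$pi_current
  bad <- which(abs(sums - 1) > 1e-9)
  if (length(bad)) {
    roi_abort("smoking_prevalence row ", bad[1], " (sex ", sp$sex[bad[1]],
              ", age ", sp$age[bad[1]], "): proportions sum to ",
              format(sums[bad[1]], digits = 10), ", not 1")
  }

  dp <- x$disease_prevalence
  check_cols(dp, c("disease", "sex", "age", "prev_all"), "disease_prevalence")
  if (!setequal(unique(dp$disease), roi_diseases)) {
    roi_abort("disease_prevalence must cover exactly the diseases ",
              paste(roi_diseases, collapse = ", "))
  }
  for (d in roi_diseases) {
    check_age_sex_coverage(dp[dp$disease == d, ],
                           ages, paste0("disease_prevalence[", d, "]"))
  }
  check_numeric_range(dp$prev_all, "disease_prevalence$prev_all", 0, 1)

  rr <- x$mortality_rr
  for (nm in c("rr_current", "rr_former")) {
    v <- rr[[nm]]$value
    if (is.null(v) || !is.numeric(v) || v <= 0) {
      roi_abort("mortality_rr$", nm, " must be a positive number")
    }
  }
  if (rr$rr_current$value < rr$rr_former$value || rr$rr_former$value < 1) {
    warning("mortality relative risks violate rr_current >= rr_former >= 1",
            call. = FALSE)
  }

  drr <- x$disease_rr
  check_cols(drr, c("disease", "rr_current", "rr_current_se",
                    "rr_former", "rr_former_se"), "disease_rr")
  if (!setequal(drr$disease, roi_diseases)) {
    roi_abort("disease_rr must cover exactly the diseases ",
              paste(roi_diseases, collapse = ", "))
  }
  check_numeric_range(drr$rr_current, "disease_rr$rr_current", 1e-12)
  check_numeric_range(drr$rr_former, "disease_rr$rr_former", 1e-12)

  dc <- x$disease_costs
  check_cols(dc, c("disease", "annual_cost", "se"), "disease_costs")
  if (!setequal(dc$disease, roi_diseases)) {
    roi_abort("disease_costs must cover exactly the diseases ",
              paste(roi_diseases, collapse = ", "))
  }
  check_numeric_range(dc$annual_cost, "disease_costs$annual_cost", 0)
  check_numeric_range(dc$se, "disease_costs$se", 0)

  ut <- x$utilities
  for (nm in c("u_current", "u_former", "u_never")) {
    v <- ut[[nm]]$value
    if (is.null(v) || !is.numeric(v) || v > 1) {
      roi_abort("utilities$", nm, " must be numeric and <= 1")
    }
  }
  if (ut$u_former$value < ut$u_current$value) {
    warning("utilities violate u_former >= u_current", call. = FALSE)
  }
  dec <- ut$decrements
  check_cols(dec, c("disease", "decrement", "se"), "utility decrements")
  if (!setequal(dec$disease, roi_diseases)) {
    roi_abort("utility decrements must cover exactly the diseases ",
              paste(roi_diseases, collapse = ", "))
  }
  check_numeric_range(dec$decrement, "utilities$decrements$decrement", 0)

  pop <- x$population
  check_cols(pop, c("sex", "age", "n_smokers"), "population")
  check_numeric_range(pop$n_smokers, "population$n_smokers", 0)
  if (sum(pop$n_smokers) <= 0) {
    roi_abort("population must contain at least one stratum with n_smokers > 0")
  }
  if (any(pop$age < st$entry_age_min | pop$age > 100)) {
    roi_abort("population ages must lie within [", st$entry_age_min, ", 100]")
  }
  if (!all(pop$sex %in% roi_sexes)) {
    roi_abort("population$sex must be one of ", paste(roi_sexes, collapse = ", "))
  }

  invisible(x)
}

#' @export
print.country_dataset <- function(x, ...) {
  st <- x$settings
  cat("<country_dataset>\n")
  cat("  ages ", st$entry_age_min, "-100, sexes male/female\n", sep = "")
  cat("  smokers: ", format(round(sum(x$population$n_smokers))),
      " across ", sum(x$population$n_smokers > 0), " strata\n", sep = "")
  cat("  discount rate ", st$discount_rate,
      ", net quit rate ", st$underlying_quit_rate,
      ", currency ", st$currency_code, "\n", sep = "")
  invisible(x)
}

dataset_files <- c(
  life_table = "life_table.csv",
  smoking_prevalence = "smoking_prevalence.csv",
  disease_prevalence = "disease_prevalence.csv",
  relative_risks = "relative_risks.csv",
  disease_costs = "disease_costs.csv",
  utilities = "utilities.csv",
  population = "population.csv",
  settings = "settings.yaml"
)

read_dataset_csv <- function(dir, file) {
  path <- file.path(dir, file)
  if (!file.exists(path)) roi_abort("dataset file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

param_value <- function(df, parameter, file) {
  i <- match(parameter, df$parameter)
  if (is.na(i)) roi_abort(file, ": missing parameter row '", parameter, "'")
  list(value = df$value[i], se = df$se[i])
}

#' Load a country dataset from a directory of delimited text files
#'
#' Reads the eight-file schema (`life_table.csv`, `smoking_prevalence.csv`,
#' `disease_prevalence.csv`, `relative_risks.csv`, `disease_costs.csv`,
#' `utilities.csv`, `population.csv`, `settings.yaml`), assembles a
#' [country_dataset()] and validates it. Standard errors for relative risks
#' are interpreted on the log scale.
#'
#' @param dir Directory holding the dataset files.
#' @param settings_override Named list of [analysis_settings()] fields that
#'   replace the values in `settings.yaml` (e.g.
#'   `list(discount_rate = 0.03)`).
#' @return A validated `country_dataset`.
#' @examples
#' dir <- tempfile()
#' write_country_dataset(generate_country_dataset(), dir)
#' ds <- load_country_dataset(dir, settings_override = list(wtp_threshold = 30000))
#' @export
load_country_dataset <- function(dir, settings_override = NULL) {
  if (!dir.exists(dir)) roi_abort("dataset directory not found: ", dir)
  spath <- file.path(dir, dataset_files[["settings"]])
  if (!file.exists(spath)) roi_abort("dataset file not found: ", spath)
  raw <- yaml::read_yaml(spath)
  for (nm in names(settings_override)) raw[[nm]] <- settings_override[[nm]]
  settings <- analysis_settings(
    discount_rate = raw$discount_rate %||% 0.035,
    underlying_quit_rate = raw$underlying_quit_rate %||% 0.02,
    horizons = raw$horizons %||% c("2", "5", "10", "lifetime"),
    wtp_threshold = raw$wtp_threshold %||% 20000,
    currency_code = raw$currency_code %||% "GBP",
    entry_age_min = raw$entry_age_min %||% 16
  )

  rrfile <- dataset_files[["relative_risks"]]
  rrdf <- read_dataset_csv(dir, rrfile)
  check_cols(rrdf, c("parameter", "value", "se"), rrfile)
  mortality_rr <- list(
    rr_current = param_value(rrdf, "rr_death_current", rrfile),
    rr_former = param_value(rrdf, "rr_death_former", rrfile)
  )
  disease_rr <- do.call(rbind, lapply(roi_diseases, function(d) {
    cur <- param_value(rrdf, paste0("rr_", d, "_current"), rrfile)
    fmr <- param_value(rrdf, paste0("rr_", d, "_former"), rrfile)
    data.frame(disease = d,
               rr_current = cur$value, rr_current_se = cur$se,
               rr_former = fmr$value, rr_former_se = fmr$se)
  }))

  utfile <- dataset_files[["utilities"]]
  utdf <- read_dataset_csv(dir, utfile)
  check_cols(utdf, c("parameter", "value", "se"), utfile)
  utilities <- list(
    u_current = param_value(utdf, "u_current", utfile),
    u_former = param_value(utdf, "u_former", utfile),
    u_never = param_value(utdf, "u_never", utfile),
    decrements = do.call(rbind, lapply(roi_diseases, function(d) {
      v <- param_value(utdf, paste0("decrement_", d), utfile)
      data.frame(disease = d, decrement = v$value, se = v$se)
    }))
  )

  country_dataset(
    life_table = read_dataset_csv(dir, dataset_files[["life_table"]]),
    smoking_prevalence = read_dataset_csv(dir, dataset_files[["smoking_prevalence"]]),
    disease_prevalence = read_dataset_csv(dir, dataset_files[["disease_prevalence"]]),
    mortality_rr = mortality_rr,
    disease_rr = disease_rr,
    disease_costs = read_dataset_csv(dir, dataset_files[["disease_costs"]]),
    utilities = utilities,
    population = read_dataset_csv(dir, dataset_files[["population"]]),
    settings = settings
  )
}

#' Write a country dataset to a directory of delimited text files
#'
#' Inverse of [load_country_dataset()]: emits the eight-file schema so that
#' reloading reproduces the dataset (bit-exact for integers, to near machine
#' precision for reals).
#'
#' @param dataset A `country_dataset`.
#' @param dir Output directory, created if absent.
#' @return `dir`, invisibly.
#' @export
write_country_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "country_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, file) {
    utils::write.csv(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                     file.path(dir, file), row.names = FALSE, quote = FALSE)
  }
  wcsv(dataset$life_table, dataset_files[["life_table"]])
  wcsv(dataset$smoking_prevalence, dataset_files[["smoking_prevalence"]])
  wcsv(dataset$disease_prevalence, dataset_files[["disease_prevalence"]])

  rr <- dataset$mortality_rr
  drr <- dataset$disease_rr
  rrdf <- rbind(
    data.frame(parameter = c("rr_death_current", "rr_death_former"),
               value = c(rr$rr_current$value, rr$rr_former$value),
               se = c(rr$rr_current$se, rr$rr_former$se)),
    do.call(rbind, lapply(seq_len(nrow(drr)), function(i) {
      data.frame(
        parameter = paste0("rr_", drr$disease[i], c("_current", "_former")),
        value = c(drr$rr_current[i], drr$rr_former[i]),
        se = c(drr$rr_current_se[i], drr$rr_former_se[i]))
    }))
  )
  wcsv(rrdf, dataset_files[["relative_risks"]])
  wcsv(dataset$disease_costs, dataset_files[["disease_costs"]])

  ut <- dataset$utilities
  utdf <- rbind(
    data.frame(parameter = c("u_current", "u_former", "u_never"),
               value = c(ut$u_current$value, ut$u_former$value, ut$u_never$value),
               se = c(ut$u_current$se, ut$u_former$se, ut$u_never$se)),
    data.frame(parameter = paste0("decrement_", ut$decrements$disease),
               value = ut$decrements$decrement,
               se = ut$decrements$se)
  )
  wcsv(utdf, dataset_files[["utilities"]])
  wcsv(dataset$population, dataset_files[["population"]])

  st <- dataset$settings
  yaml::write_yaml(
    list(discount_rate = st$discount_rate,
         underlying_quit_rate = st$underlying_quit_rate,
         horizons = as.list(st$horizons),
         wtp_threshold = st$wtp_threshold,
         currency_code = st$currency_code,
         entry_age_min = st$entry_age_min),
    file.path(dir, dataset_files[["settings"]])
  )
  invisible(dir)
}

#' Define a single cessation intervention
#'
#' @param name Label.
#' @param uptake Proportion of quit attempters who use the intervention,
#'   in `[0, 1]`. Population-level interventions that only shift the attempt
#'   rate use `uptake = 0`.
#' @param rr_success Relative risk of a successful quit versus an unaided
#'   attempt (`> 0`).
#' @param cost_per_use Currency cost per attempt that uses the intervention.
#' @param attempt_rate_multiplier Relative change in the proportion of
#'   smokers making a quit attempt (1 = no change).
#' @param fixed_cost Lump-sum currency cost independent of use.
#' @return A list of class `roi_intervention`.
#' @export
intervention <- function(name, uptake = 0, rr_success = 1, cost_per_use = 0,
                         attempt_rate_multiplier = 1, fixed_cost = 0) {
  check_numeric_range(uptake, paste0("intervention '", name, "' uptake"), 0, 1)
  if (rr_success <= 0) roi_abort("intervention '", name, "': rr_success must be > 0")
  check_numeric_range(cost_per_use, paste0("intervention '", name, "' cost_per_use"), 0)
  check_numeric_range(attempt_rate_multiplier,
                      paste0("intervention '", name, "' attempt_rate_multiplier"), 0)
  check_numeric_range(fixed_cost, paste0("intervention '", name, "' fixed_cost"), 0)
  structure(list(name = name, uptake = uptake, rr_success = rr_success,
                 cost_per_use = cost_per_use,
                 attempt_rate_multiplier = attempt_rate_multiplier,
                 fixed_cost = fixed_cost),
            class = "roi_intervention")
}

#' Define a package of cessation interventions
#'
#' A package couples a baseline quit-attempt rate and unaided success
#' probability with zero or more [intervention()]s. The "status quo" package
#' has an empty intervention list.
#'
#' @param name Label.
#' @param interventions List of [intervention()] objects.
#' @param baseline_attempt_rate Proportion of the smoking cohort making a
#'   quit attempt in the first year, before any attempt-rate multipliers.
#' @param unaided_success Probability that an unaided quit attempt succeeds.
#' @return A list of class `package_spec`.
#' @seealso [first_cycle_quit_probability()], [evaluate_package()]
#' @export
package_spec <- function(name, interventions = list(),
                         baseline_attempt_rate, unaided_success) {
  interventions <- lapply(interventions, function(iv) {
    if (inherits(iv, "roi_intervention")) iv else do.call(intervention, iv)
  })
  check_numeric_range(baseline_attempt_rate, "baseline_attempt_rate", 0, 1)
  check_numeric_range(unaided_success, "unaided_success", 0, 1)
  uptakes <- vapply(interventions, `[[`, numeric(1), "uptake")
  if (length(uptakes) && sum(uptakes) > 1 + 1e-12) {
    roi_abort("package '", name, "': intervention uptakes sum to ",
              format(sum(uptakes)), " (> 1)")
  }
  x <- structure(list(name = name, interventions = interventions,
                      baseline_attempt_rate = baseline_attempt_rate,
                      unaided_success = unaided_success),
                 class = "package_spec")
  aeff <- effective_attempt_rate(x)
  if (aeff > 1 + 1e-12) {
    roi_abort("package '", name, "': effective attempt rate ", format(aeff),
              " exceeds 1")
  }
  x
}

#' Effective first-year quit-attempt rate of a package
#'
#' Baseline attempt rate multiplied by every intervention's
#' `attempt_rate_multiplier`.
#'
#' @param package A [package_spec()].
#' @return Proportion in `[0, 1]`.
#' @export
effective_attempt_rate <- function(package) {
  stopifnot(inherits(package, "package_spec"))
  mult <- prod(vapply(package$interventions, `[[`, numeric(1),
                      "attempt_rate_multiplier"))
  package$baseline_attempt_rate * mult
}

#' @export
print.package_spec <- function(x, ...) {
  cat("<package_spec> ", x$name, "\n", sep = "")
  cat("  attempt rate ", x$baseline_attempt_rate,
      " (effective ", format(effective_attempt_rate(x)), ")",
      ", unaided success ", x$unaided_success, "\n", sep = "")
  for (iv in x$interventions) {
    cat(sprintf("  - %s: uptake %.3g, RR %.3g, %s/use %.6g, fixed %.6g\n",
                iv$name, iv$uptake, iv$rr_success, "cost", iv$cost_per_use,
                iv$fixed_cost))
  }
  invisible(x)
}

#' Load a package specification from a YAML or JSON file
#'
#' @param path File with fields `name`, `baseline_attempt_rate`,
#'   `unaided_success` and an optional `interventions` list, each entry
#'   holding [intervention()] fields.
#' @return A validated [package_spec()].
#' @export
load_package_spec <- function(path) {
  if (!file.exists(path)) roi_abort("package file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw$name) || is.null(raw$baseline_attempt_rate) ||
      is.null(raw$unaided_success)) {
    roi_abort(path, ": package file needs name, baseline_attempt_rate and ",
              "unaided_success")
  }
  package_spec(
    name = raw$name,
    interventions = lapply(raw$interventions %||% list(), function(iv) {
      intervention(name = iv$name %||% "intervention",
                   uptake = iv$uptake %||% 0,
                   rr_success = iv$rr_success %||% 1,
                   cost_per_use = iv$cost_per_use %||% 0,
                   attempt_rate_multiplier = iv$attempt_rate_multiplier %||% 1,
                   fixed_cost = iv$fixed_cost %||% 0)
    }),
    baseline_attempt_rate = raw$baseline_attempt_rate,
    unaided_success = raw$unaided_success
  )
}

#' Write a package specification to YAML
#'
#' @param package A [package_spec()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_package_spec <- function(package, path) {
  stopifnot(inherits(package, "package_spec"))
  yaml::write_yaml(
    list(name = package$name,
         baseline_attempt_rate = package$baseline_attempt_rate,
         unaided_success = package$unaided_success,
         interventions = lapply(package$interventions, unclass)),
    path
  )
  invisible(path)
}
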