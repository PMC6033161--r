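# Run configuration, report files and the plumbing behind the command-line
# wrapper (inst/cli/roi.R).

roi_version <- function() {
  as.character(utils::packageVersion("quitroi"))
}

dataset_checksum <- function(dataset_dir) {
  if (is.null(dataset_dir) || !dir.exists(dataset_dir)) return(NA_character_)
  files <- sort(list.files(dataset_dir, full.names = TRUE))
  sums <- tools::md5sum(files)
  # checksum of the concatenated per-file checksums, via a temp file
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(names(sums), sums), tmp)
  unname(tools::md5sum(tmp))
}

write_report_csv <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header), con)
  utils::write.csv(df, con, row.names = FALSE)
}

resolve_dataset <- function(dataset, settings_override = NULL) {
  if (inherits(dataset, "country_dataset")) {
    list(dataset = dataset, dir = NULL)
  } else {
    list(dataset = load_country_dataset(dataset, settings_override),
         dir = dataset)
  }
}

resolve_packages <- function(packages) {
  pk <- lapply(packages, function(p) {
    if (inherits(p, "package_spec")) p else load_package_spec(p)
  })
  if (length(pk) < 1 || length(pk) > 3) {
    roi_abort("between 1 and 3 packages can be considered at any one time")
  }
  pk
}

#' Run the deterministic analysis and write report files
#'
#' Runs both quit scenarios over all strata, evaluates each package at every
#' configured horizon, compares each package against the first, and writes
#' `outcomes.csv`, `package_results.csv`, `comparisons.csv` and
#' `summary.json` into `out_dir`. Every file carries a header recording the
#' tool version, seed and dataset checksum so a run can be reproduced
#' exactly.
#'
#' @param dataset A [country_dataset()] or the path of a dataset directory.
#' @param packages List (length 1-3) of [package_spec()]s or file paths;
#'   the first is the comparator. With a single package no comparisons are
#'   written.
#' @param out_dir Output directory, created if needed.
#' @param settings_override Optional settings overrides applied when
#'   `dataset` is a path (see [load_country_dataset()]).
#' @param seed Seed recorded in the report header (the deterministic run
#'   itself uses no randomness).
#' @return Invisibly, a list with the scenario outcomes, package results
#'   and comparisons.
#' @export
run_deterministic <- function(dataset, packages, out_dir,
                              settings_override = NULL, seed = NA) {
  rs <- resolve_dataset(dataset, settings_override)
  ds <- rs$dataset
  pk <- resolve_packages(packages)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(out_dir, mode = 2) != 0) {
    roi_abort("output directory is not writable: ", out_dir)
  }
  header <- paste0("quitroi ", roi_version(), "; seed ", seed,
                   "; dataset md5 ", dataset_checksum(rs$dir))

  outcomes <- run_scenarios(ds)
  horizons <- ds$settings$horizons
  results <- list()
  for (p in pk) {
    for (h in horizons) {
      res <- evaluate_package(p, outcomes, horizon = h)
      results[[length(results) + 1L]] <- res
    }
  }
  res_df <- do.call(rbind, lapply(results, function(r) {
    data.frame(package = r$package$name, horizon = r$horizon,
               quit_prob = r$quit_prob,
               intervention_cost = r$intervention_cost_total,
               expected_cost = r$expected_cost,
               expected_qalys = r$expected_qalys,
               expected_life_years = r$expected_life_years,
               expected_deaths = r$expected_deaths)
  }))

  comparisons <- list()
  if (length(pk) > 1) {
    for (h in horizons) {
      base <- evaluate_package(pk[[1]], outcomes, horizon = h)
      for (p in pk[-1]) {
        comparisons[[length(comparisons) + 1L]] <- compare_packages(
          base, evaluate_package(p, outcomes, horizon = h),
          threshold = ds$settings$wtp_threshold)
      }
    }
  }

  tmp_out <- file.path(out_dir, "outcomes.csv")
  popn <- as.data.frame(outcomes$population)
  per <- outcomes$per_stratum
  write_report_csv(per, tmp_out, header)
  write_report_csv(popn, file.path(out_dir, "population_outcomes.csv"), header)
  write_report_csv(res_df, file.path(out_dir, "package_results.csv"), header)
  if (length(comparisons)) {
    comp_df <- do.call(rbind, lapply(comparisons, as.data.frame))
    write_report_csv(comp_df, file.path(out_dir, "comparisons.csv"), header)
  } else comp_df <- NULL

  jsonlite::write_json(
    list(tool = "quitroi", version = roi_version(), seed = seed,
         dataset_md5 = dataset_checksum(rs$dir),
         n_smokers = outcomes$n_smokers,
         currency = ds$settings$currency_code,
         packages = vapply(pk, `[[`, character(1), "name"),
         population_outcomes = popn,
         comparisons = comp_df),
    file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, na = "null", digits = NA)
  invisible(list(outcomes = outcomes, results = res_df,
                 comparisons = comparisons))
}

#' Run the probabilistic analysis and write report files
#'
#' Runs [run_psa()] and writes `scatter.csv` (one row per replicate),
#' `ceac.csv` and `summary.json` into `out_dir`. Outputs are byte-identical
#' across reruns with the same seed.
#'
#' @param dataset A [country_dataset()] or dataset directory path.
#' @param packages List (length 2-3) of [package_spec()]s or file paths.
#' @param out_dir Output directory.
#' @param n_reps Monte Carlo replications (default 1000).
#' @param seed Master seed.
#' @param thresholds CEAC threshold grid.
#' @param settings_override Optional settings overrides for a dataset path.
#' @return Invisibly, the `psa_replicates` object.
#' @export
run_psa_command <- function(dataset, packages, out_dir, n_reps = 1000,
                            seed = 1, thresholds = seq(0, 50000, by = 1000),
                            settings_override = NULL) {
  rs <- resolve_dataset(dataset, settings_override)
  pk <- resolve_packages(packages)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  header <- paste0("quitroi ", roi_version(), "; seed ", seed,
                   "; dataset md5 ", dataset_checksum(rs$dir))

  reps <- run_psa(rs$dataset, pk, n_reps = n_reps, seed = seed)
  sc <- export_scatter(reps)
  cc <- ceac(reps, thresholds)
  write_report_csv(sc, file.path(out_dir, "scatter.csv"), header)
  write_report_csv(as.data.frame(cc), file.path(out_dir, "ceac.csv"), header)
  jsonlite::write_json(
    list(tool = "quitroi", version = roi_version(), seed = seed,
         dataset_md5 = dataset_checksum(rs$dir),
         n_reps = n_reps, comparator = attr(reps, "comparator"),
         horizon = attr(reps, "horizon"),
         means = attr(sc, "summary")),
    file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, na = "null", digits = NA)
  invisible(reps)
}
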