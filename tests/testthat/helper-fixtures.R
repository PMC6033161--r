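# Shared fixtures and independent oracles used across the suite.

# Compact dataset: five entry ages, traces of about 40 cycles.
small_fixture <- function(seed = 1, ...) {
  generate_country_dataset(fixture_params(seed = seed, entry_age_min = 60,
                                          entry_age_max = 64, ...))
}

# Minimal dataset: three entry ages, traces under 20 cycles (PSA tests).
tiny_fixture <- function(seed = 1, ...) {
  generate_country_dataset(fixture_params(seed = seed, entry_age_min = 82,
                                          entry_age_max = 84, ...))
}

# Dataset with every sampled standard error zeroed, for fixed-parameter PSA.
all_fixed_fixture <- function(seed = 1, ...) {
  ds <- tiny_fixture(seed = seed, ...)
  ds$mortality_rr$rr_current$se <- 0
  ds$mortality_rr$rr_former$se <- 0
  ds$disease_rr$rr_current_se <- 0
  ds$disease_rr$rr_former_se <- 0
  ds$disease_costs$se <- 0
  for (nm in c("u_current", "u_former", "u_never")) ds$utilities[[nm]]$se <- 0
  ds$utilities$decrements$se <- 0
  ds
}

# Independent matrix-power oracle for the cohort engine: occupancy advanced
# by explicit 3x3 transition matrices.
transition_matrix <- function(p_c, p_f, q) {
  rbind(
    c((1 - p_c) * (1 - q), (1 - p_c) * q, p_c),
    c(0, 1 - p_f, p_f),
    c(0, 0, 1)
  )
}

matrix_oracle_trace <- function(start_age, sex, scenario, dataset,
                                q_net = NULL) {
  if (is.null(q_net)) q_net <- net_quit_probability(dataset)
  sm <- status_mortality(dataset)
  ages <- start_age:100
  rows <- match(paste(sex, ages), paste(sm$sex, sm$age))
  occ <- matrix(0, nrow = length(ages), ncol = 3)
  occ[1, ] <- if (scenario == "quit_first_cycle") c(0, 1, 0) else c(1, 0, 0)
  for (t in seq_len(length(ages) - 1)) {
    M <- transition_matrix(sm$p_current[rows[t]], sm$p_former[rows[t]], q_net)
    occ[t + 1, ] <- occ[t, ] %*% M
  }
  occ
}

# Brute-force oracle for the max-decrement comorbidity rule: enumerate all
# 2^k disease subsets.
enumerate_max_decrement <- function(prev, dec) {
  k <- length(prev)
  total <- 0
  for (mask in 0:(2^k - 1)) {
    present <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1)))
    p <- prod(ifelse(present, prev, 1 - prev))
    loss <- if (any(present)) max(dec[present]) else 0
    total <- total + p * loss
  }
  total
}

worked_example_results <- function(we = england_worked_example()) {
  lapply(we$packages, evaluate_package, outcomes = we$outcomes,
         n_smokers = we$n_smokers)
}
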