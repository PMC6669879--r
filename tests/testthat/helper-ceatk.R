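# Shared fixtures and independent oracles.

# Independent tariff oracle: scalar arithmetic with the UK coefficient
# table transcribed directly, kept deliberately separate from the package's
# vectorised scoring path.
oracle_uk_utility <- function(levels) {
  mo <- c(0, 0.069, 0.314); sc <- c(0, 0.104, 0.214)
  ua <- c(0, 0.036, 0.094); pd <- c(0, 0.123, 0.386)
  ad <- c(0, 0.071, 0.236)
  if (all(levels == 1)) return(1)
  u <- 1 - 0.081 -
    mo[levels[1]] - sc[levels[2]] - ua[levels[3]] -
    pd[levels[4]] - ad[levels[5]]
  if (any(levels == 3)) u <- u - 0.269
  u
}

# Independent trapezoid oracle: explicit interval-by-interval sum.
oracle_trapezoid_qaly <- function(times, utilities) {
  total <- 0
  for (i in seq_len(length(times) - 1)) {
    total <- total +
      (times[i + 1] - times[i]) * (utilities[i] + utilities[i + 1]) / 2
  }
  total / 12
}

# Small complete trial and analysis table reused across test files
# (built once per test run).
small_trial <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- trial_design(n_intervention = 40, n_control = 20, seed = 101,
                        true_effects = sim_truth(missing_fraction = 0))
      cache <<- generate_trial(d)
    }
    cache
  }
})

demo_result <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- trial_design(seed = 101)
      ana <- build_analysis_table(simulate_trial(d))
      cache <<- cea_analysis(ana, m = 5, B = 200, seed = 7)
    }
    cache
  }
})

# A deterministic mock bootstrap cloud.
mock_cloud <- function(delta_cost, delta_effect) {
  n <- max(length(delta_cost), length(delta_effect))
  tibble::tibble(
    imputation = 1L, replicate = seq_len(n),
    delta_cost = rep_len(delta_cost, n),
    delta_effect = rep_len(delta_effect, n)
  )
}
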