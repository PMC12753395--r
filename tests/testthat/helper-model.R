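# Shared builders for the two-arm surgical model used across tests.

baseline_config <- function() {
  load_config(system.file("extdata", "paper_baseline.yaml", package = "pdcea"))
}

# both arms with per-cycle costs calibrated to the configured cumulative
# cost targets
baseline_strategies <- function() {
  res <- run_cea(baseline_config())
  list(reference = res$reference$params, comparator = res$comparator$params,
       result = res)
}

# printed cost-effectiveness table used as worked-example inputs
reported_results <- function() {
  rep <- baseline_config()$reported
  list(reference = econ_result("OPD", rep$reference$total_cost,
                               rep$reference$qalys),
       comparator = econ_result("LPD", rep$comparator$total_cost,
                                rep$comparator$qalys))
}

# a psa_result restricted to draws satisfying a predicate (for conditional
# CEAC properties)
subset_psa <- function(ps, keep) {
  ps$draws <- ps$draws[keep, , drop = FALSE]
  ps$n_draws <- nrow(ps$draws)
  ps
}
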