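# Shared fixtures: the bundled depression model and small hand-built
# scenarios used across test files.

depr <- depression_config()
depr_specs <- config_scenarios(depr)
depr_run <- run_model(depr)

# expected full-precision chain for a scenario, computed independently of
# evaluate_cascade by sequential scalar multiplication
chain_oracle <- function(population, proportions) {
  out <- numeric(length(proportions))
  cur <- population
  for (i in seq_along(proportions)) {
    cur <- cur * proportions[i]
    out[i] <- cur
  }
  out
}

toy_scenario <- function(label = "toy", population = 1000,
                         p = c(0.5, 0.2), cost = c(0, 0)) {
  scenario_spec(label, population, lapply(seq_along(p), function(i)
    step_spec(sprintf("s%d", i), p[i], unit_cost = cost[i])))
}
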