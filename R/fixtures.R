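#' The bundled depression-in-primary-care worked example
#'
#' A national-scale filter model of depression management in Australian
#' general practice: the adult population is filtered through depression
#' prevalence (8.9%), annual GP attendance (81%), GP detection (47%), offer
#' of evidence-based treatment ("reach", 28%), patient adherence (51%) and
#' six-month remission (37%). Three hypothetical intervention scenarios each
#' improve one filter at a per-person cost: routine waiting-room depression
#' screening (detection 77%, $5), GP education and training (reach 69%,
#' $247) and telephone follow-up of patients in treatment (adherence 65%,
#' $98). All amounts are AUD.
#'
#' @return A `model_config` with four scenarios (baseline, filter1,
#'   filter2, filter3) over six steps and a population of 15,055,403.
#' @examples
#' run <- run_model(depression_config())
#' round_for_report(run$comparisons$filter1$icer, "currency")  # 243
#' @export
depression_config <- function() {
  load_config(depression_config_path())
}

#' Path to the bundled depression example configuration file
#'
#' @return Path to the YAML config shipped with the package; useful as a
#'   template for new models (also emitted by the `example` CLI
#'   subcommand).
#' @export
depression_config_path <- function() {
  system.file("extdata", "depression.yaml", package = "filtercascade",
              mustWork = TRUE)
}

#' Generate a random scenario for property testing
#'
#' Deterministic given `seed`: step count uniform over `n_steps_range`,
#' proportions uniform in `[0, 1]`, unit costs uniform in `cost_range`,
#' population uniform in `[1, 10^7]`.
#'
#' @param seed Integer seed.
#' @param n_steps_range Integer length-2 vector, inclusive range for the
#'   number of steps (default `c(1, 8)`).
#' @param cost_range Numeric length-2 vector, range for unit costs (default
#'   `c(0, 100)`).
#' @return A valid [scenario_spec()].
#' @export
random_scenario <- function(seed, n_steps_range = c(1L, 8L),
                            cost_range = c(0, 100)) {
  stopifnot(length(n_steps_range) == 2L, n_steps_range[1] >= 1L,
            n_steps_range[1] <= n_steps_range[2],
            length(cost_range) == 2L, cost_range[1] >= 0,
            cost_range[1] <= cost_range[2])
  with_local_seed(seed, {
    n <- sample(seq.int(n_steps_range[1], n_steps_range[2]), 1L)
    steps <- lapply(seq_len(n), function(i)
      step_spec(sprintf("step%02d", i),
                proportion = stats::runif(1),
                unit_cost = stats::runif(1, cost_range[1], cost_range[2])))
    scenario_spec(sprintf("random_%d", seed),
                  population = stats::runif(1, 1, 1e7), steps)
  })
}

#' Individual-level Bernoulli microsimulation of a cascade
#'
#' Realises the cascade's independence assumption at the individual level:
#' each of `n_individuals` passes step *i* independently with probability
#' equal to the step's proportion, and costs accrue per costed individual
#' at the step's cost basis. This is a validation oracle for the
#' cohort-expectation model (and an optional CLI feature), not the primary
#' computation path: empirical pass fractions converge to the product of
#' proportions binomially.
#'
#' @param scenario A [scenario_spec()]; its `population` field is ignored
#'   in favour of `n_individuals`.
#' @param n_individuals Number of simulated individuals (`>= 1`).
#' @param seed Integer seed; recorded in the result for reproducibility.
#' @return An object of class `microsim_result`: `n_individuals`,
#'   `pass_counts` (integer persons surviving each step), `successes`,
#'   `total_cost`, `seed`.
#' @examples
#' sc <- scenario_spec("toy", 1, list(step_spec("s", 0.5)))
#' microsimulate(sc, 1000, seed = 42)
#' @export
microsimulate <- function(scenario, n_individuals, seed) {
  stopifnot(inherits(scenario, "scenario_spec"), n_individuals >= 1)
  validate_scenario_spec(scenario)
  n_individuals <- as.integer(n_individuals)
  with_local_seed(seed, {
    alive <- n_individuals
    k <- length(scenario$steps)
    pass_counts <- integer(k)
    total_cost <- 0
    for (i in seq_len(k)) {
      st <- scenario$steps[[i]]
      passed <- stats::rbinom(1L, alive, st$proportion)
      costed <- if (st$cost_basis == "post_step") passed else alive
      total_cost <- total_cost + st$unit_cost * costed
      pass_counts[i] <- passed
      alive <- passed
    }
    structure(list(n_individuals = n_individuals,
                   pass_counts = stats::setNames(pass_counts,
                                                 step_labels(scenario)),
                   successes = pass_counts[k],
                   total_cost = total_cost,
                   seed = seed),
              class = "microsim_result")
  })
}

#' @export
print.microsim_result <- function(x, ...) {
  cat(sprintf("<microsim_result> n = %s, seed = %d\n",
              format(x$n_individuals, big.mark = ","), x$seed))
  print(x$pass_counts)
  cat(sprintf("successes: %s   total cost: %s\n",
              format(x$successes, big.mark = ","),
              format(x$total_cost, big.mark = ",")))
  invisible(x)
}
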