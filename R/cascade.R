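#' Apply one filter step to an expected person-count
#'
#' Computes the expected number of persons passing the filter and the step's
#' intervention cost. All arithmetic is carried at full floating-point
#' precision; rounding happens only at report time (see
#' [round_for_report()]).
#'
#' @param entering Expected persons entering the step (real, `>= 0`).
#' @param step A [step_spec()].
#'
#' @return A `step_result` list with fields `label`, `entering`,
#'   `proportion`, `resulting` (`entering * proportion`), `unit_cost`,
#'   `cost_basis` and `step_cost` (`unit_cost` times the count at the cost
#'   basis).
#' @examples
#' apply_step(1085344, step_spec("detection", 0.47))
#' @export
apply_step <- function(entering, step) {
  stopifnot(inherits(step, "step_spec"))
  if (length(entering) != 1L || is.na(entering) || !is.finite(entering) ||
      entering < 0)
    stop("entering count must be a finite non-negative number", call. = FALSE)
  resulting <- entering * step$proportion
  costed <- if (step$cost_basis == "post_step") resulting else entering
  structure(
    list(label = step$label,
         entering = entering,
         proportion = step$proportion,
         resulting = resulting,
         unit_cost = step$unit_cost,
         cost_basis = step$cost_basis,
         is_intervention = step$is_intervention,
         step_cost = step$unit_cost * costed),
    class = "step_result")
}

#' Evaluate a full filter cascade
#'
#' Chains the scenario's steps: the resulting count of step *i* is the
#' entering count of step *i + 1*; the final resulting count is the expected
#' number of successful outcomes. Expected counts are continuous reals (a
#' cohort-expectation model, not a microsimulation) and equal
#' `population * prod(proportions)` up to floating precision.
#'
#' @param scenario A [scenario_spec()].
#'
#' @return An object of class `cascade_result` with:
#' \describe{
#'   \item{scenario_label, population, currency}{copied from the scenario}
#'   \item{steps}{data frame with one row per step: `label`, `entering`,
#'     `proportion`, `resulting`, `unit_cost`, `cost_basis`, `step_cost`,
#'     `is_intervention`}
#'   \item{successes}{expected persons achieving the final outcome}
#'   \item{total_cost}{sum of step costs}
#'   \item{cost_per_exposed}{see [cost_per_exposed()]}
#'   \item{cost_per_success}{see [cost_per_success()]}
#' }
#' @examples
#' sc <- scenario_spec("toy", 100, list(step_spec("only", 1)))
#' evaluate_cascade(sc)$successes  # 100
#' @export
evaluate_cascade <- function(scenario) {
  stopifnot(inherits(scenario, "scenario_spec"))
  validate_scenario_spec(scenario)
  n <- length(scenario$steps)
  p <- vapply(scenario$steps, `[[`, numeric(1), "proportion")
  uc <- vapply(scenario$steps, `[[`, numeric(1), "unit_cost")
  cb <- vapply(scenario$steps, `[[`, character(1), "cost_basis")
  # sequential products so that resulting[i] == entering[i] * p[i] exactly
  resulting <- numeric(n)
  cur <- scenario$population
  for (i in seq_len(n)) {
    cur <- cur * p[i]
    resulting[i] <- cur
  }
  entering <- c(scenario$population, resulting[-n])[seq_len(n)]
  steps <- data.frame(
    label = vapply(scenario$steps, `[[`, character(1), "label"),
    entering = entering, proportion = p, resulting = resulting,
    unit_cost = uc, cost_basis = cb,
    step_cost = uc * ifelse(cb == "post_step", resulting, entering),
    is_intervention = vapply(scenario$steps, `[[`, logical(1),
                             "is_intervention"),
    stringsAsFactors = FALSE)
  res <- structure(
    list(scenario_label = scenario$label,
         population = scenario$population,
         currency = scenario$currency,
         steps = steps,
         successes = steps$resulting[n],
         total_cost = sum(steps$step_cost)),
    class = "cascade_result")
  res$cost_per_exposed <- cost_per_exposed(res)
  res$cost_per_success <- cost_per_success(res)
  res
}

#' @export
print.cascade_result <- function(x, ...) {
  cat(sprintf("<cascade_result> scenario '%s' (population %s)\n",
              x$scenario_label,
              format(round(x$population), big.mark = ",")))
  df <- x$steps
  df$entering <- format(round(df$entering), big.mark = ",")
  df$resulting <- format(round(df$resulting), big.mark = ",")
  df$step_cost <- format(round(df$step_cost), big.mark = ",")
  print(df[, c("label", "proportion", "unit_cost", "entering", "resulting",
               "step_cost")], row.names = FALSE)
  cat(sprintf("successes: %s   total cost: %s %s\n",
              format(round(x$successes), big.mark = ","), x$currency,
              format(round(x$total_cost), big.mark = ",")))
  invisible(x)
}
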