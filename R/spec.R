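#' Define a single filter step
#'
#' A filter step passes a fixed proportion of its entrants on to the next
#' step of the cascade and may carry an intervention unit cost. The cost is
#' multiplied by the expected person-count at the chosen basis: `"post_step"`
#' (the count *after* the filter is applied, the default) or `"pre_step"`
#' (the count entering the step, e.g. a screening cost paid for everyone
#' screened, not only those screening positive).
#'
#' @param label Short unique identifier for the step (e.g. `"detection"`).
#' @param proportion Fraction in `[0, 1]` of entrants passing the filter.
#' @param unit_cost Intervention cost per costed person (currency units,
#'   `>= 0`). Default 0 (no intervention at this step).
#' @param cost_basis Which count the unit cost multiplies: `"post_step"`
#'   (default) or `"pre_step"`.
#' @param description Free-text description for reports.
#' @param is_intervention Flag marking the step an intervention scenario
#'   modifies; used for reporting only, never in the arithmetic.
#'
#' @return An object of class `step_spec`.
#' @examples
#' step_spec("detection", 0.47)
#' step_spec("detection", 0.77, unit_cost = 5, is_intervention = TRUE)
#' @export
step_spec <- function(label, proportion, unit_cost = 0,
                      cost_basis = c("post_step", "pre_step"),
                      description = "", is_intervention = FALSE) {
  cost_basis <- match.arg(cost_basis)
  x <- structure(
    list(label = as.character(label),
         description = as.character(description),
         proportion = as.numeric(proportion),
         unit_cost = as.numeric(unit_cost),
         cost_basis = cost_basis,
         is_intervention = isTRUE(is_intervention)),
    class = "step_spec")
  validate_step_spec(x)
  x
}

validate_step_spec <- function(x) {
  problems <- character(0)
  if (length(x$label) != 1L || is.na(x$label) || !nzchar(x$label))
    problems <- c(problems, "label must be a non-empty string")
  if (length(x$proportion) != 1L || is.na(x$proportion) ||
      x$proportion < 0 || x$proportion > 1)
    problems <- c(problems, sprintf(
      "step '%s': proportion must lie in [0, 1], got %s",
      x$label, format(x$proportion)))
  if (length(x$unit_cost) != 1L || is.na(x$unit_cost) || x$unit_cost < 0)
    problems <- c(problems, sprintf(
      "step '%s': unit_cost must be >= 0, got %s",
      x$label, format(x$unit_cost)))
  if (length(problems))
    stop("invalid step_spec:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  invisible(x)
}

#' Define a scenario: a population and an ordered cascade of filter steps
#'
#' A scenario is one column of a filter model: a starting population and the
#' ordered filters it flows through. Scenarios are compared against whichever
#' scenario the user designates as baseline (usual care).
#'
#' @param label Scenario name (e.g. `"baseline"`, `"filter1"`).
#' @param population Positive number of persons entering the cascade.
#' @param steps List of [step_spec()] objects, length >= 1, with unique
#'   labels.
#' @param currency Currency label used in reports (default `"AUD"`).
#'
#' @return An object of class `scenario_spec`.
#' @examples
#' scenario_spec("toy", 1000, list(
#'   step_spec("prevalence", 0.1),
#'   step_spec("detected", 0.5, unit_cost = 2)))
#' @export
scenario_spec <- function(label, population, steps, currency = "AUD") {
  if (inherits(steps, "step_spec")) steps <- list(steps)
  x <- structure(
    list(label = as.character(label),
         population = as.numeric(population),
         steps = steps,
         currency = as.character(currency)),
    class = "scenario_spec")
  validate_scenario_spec(x)
  x
}

validate_scenario_spec <- function(x) {
  problems <- character(0)
  if (length(x$population) != 1L || is.na(x$population) ||
      !is.finite(x$population) || x$population <= 0)
    problems <- c(problems, sprintf(
      "population must be a positive finite number, got %s",
      format(x$population)))
  if (!is.list(x$steps) || length(x$steps) < 1L)
    problems <- c(problems, "steps must contain at least one step_spec")
  else {
    ok <- vapply(x$steps, inherits, logical(1), what = "step_spec")
    if (!all(ok))
      problems <- c(problems, "every element of steps must be a step_spec")
    else {
      labs <- vapply(x$steps, `[[`, character(1), "label")
      if (anyDuplicated(labs))
        problems <- c(problems, paste0(
          "step labels must be unique; duplicated: ",
          paste(unique(labs[duplicated(labs)]), collapse = ", ")))
      for (s in x$steps) {
        chk <- tryCatch({validate_step_spec(s); NULL},
                        error = function(e) conditionMessage(e))
        if (!is.null(chk)) problems <- c(problems, chk)
      }
    }
  }
  if (length(problems))
    stop(sprintf("invalid scenario '%s':\n  ", x$label),
         paste(problems, collapse = "\n  "), call. = FALSE)
  invisible(x)
}

step_labels <- function(scenario) {
  vapply(scenario$steps, `[[`, character(1), "label")
}

#' @export
print.step_spec <- function(x, ...) {
  cat(sprintf("<step_spec> %s: proportion %.4g", x$label, x$proportion))
  if (x$unit_cost > 0)
    cat(sprintf(", unit cost %.4g (%s)", x$unit_cost, x$cost_basis))
  if (x$is_intervention) cat(" [intervention]")
  cat("\n")
  invisible(x)
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("<scenario_spec> '%s': population %s, %d steps (%s)\n",
              x$label, format(x$population, big.mark = ","),
              length(x$steps), x$currency))
  for (s in x$steps)
    cat(sprintf("  %-24s p = %-8.4g unit cost = %.4g [%s]\n",
                s$label, s$proportion, s$unit_cost, s$cost_basis))
  invisible(x)
}
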