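#' Load a filter-model configuration file
#'
#' Configurations are YAML documents that replace the spreadsheet a filter
#' model is traditionally built in. The schema (version 1):
#'
#' ```yaml
#' schema_version: 1
#' currency: AUD
#' population: {label: ..., size: 15055403}
#' baseline: baseline          # name of the comparator scenario
#' steps:                      # ordered filter definitions
#'   - {label: detection, description: ..., proportion: 0.47, unit_cost: 0,
#'      cost_basis: post_step}
#' scenarios:                  # sparse overrides of the step parameters
#'   baseline: {}
#'   filter1:
#'     overrides:
#'       detection: {proportion: 0.77, unit_cost: 5, is_intervention: true}
#' bounds:                     # optional interval analysis
#'   - {scenario: filter1, step: detection, field: proportion,
#'      lower: 0.47, upper: 0.77}
#' report: {rounding: true, format: table}
#' ```
#'
#' Scenarios are expressed as sparse overrides of the shared step list
#' rather than full copies, matching the "no change to baseline" idiom of
#' scenario tables and preventing transcription drift.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated object of class `model_config`.
#' @seealso [write_config()], [config_scenario()], [run_model()]
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  raw <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop("config parse error in '", path, "': ", conditionMessage(e),
         call. = FALSE))
  as_model_config(raw)
}

#' Build a model_config from an R list
#'
#' Accepts the same structure [load_config()] reads from YAML; applies
#' defaults and validates every field, reporting failures with their field
#' path.
#'
#' @param raw A named list following the config schema.
#' @return A validated `model_config`.
#' @export
as_model_config <- function(raw) {
  problems <- character(0)
  note <- function(...) problems <<- c(problems, sprintf(...))

  if (is.null(raw$schema_version)) raw$schema_version <- 1L
  if (!identical(as.integer(raw$schema_version), 1L))
    note("schema_version: unsupported version '%s' (expected 1)",
         format(raw$schema_version))
  currency <- if (is.null(raw$currency)) "AUD" else as.character(raw$currency)

  pop <- raw$population
  if (is.null(pop) || is.null(pop$size)) {
    note("population.size: required")
    pop_size <- NA_real_
  } else pop_size <- as.numeric(pop$size)
  if (!is.na(pop_size) && (!is.finite(pop_size) || pop_size <= 0))
    note("population.size: must be a positive number, got %s",
         format(pop_size))
  pop_label <- if (is.null(pop$label)) "population" else as.character(pop$label)

  steps <- raw$steps
  if (is.null(steps) || length(steps) < 1L) {
    note("steps: at least one step is required")
    steps <- list()
  }
  step_defs <- vector("list", length(steps))
  for (i in seq_along(steps)) {
    s <- steps[[i]]
    pfx <- sprintf("steps[%d]", i)
    if (is.null(s$label)) note("%s.label: required", pfx)
    if (is.null(s$proportion)) note("%s.proportion: required", pfx)
    else {
      p <- as.numeric(s$proportion)
      if (!is.finite(p) || p < 0 || p > 1)
        note("%s (%s).proportion: must lie in [0, 1], got %s", pfx,
             if (is.null(s$label)) "?" else s$label, format(p))
    }
    uc <- if (is.null(s$unit_cost)) 0 else as.numeric(s$unit_cost)
    if (!is.finite(uc) || uc < 0)
      note("%s.unit_cost: must be >= 0, got %s", pfx, format(uc))
    cb <- if (is.null(s$cost_basis)) "post_step" else as.character(s$cost_basis)
    if (!cb %in% c("post_step", "pre_step"))
      note("%s.cost_basis: must be post_step or pre_step, got '%s'", pfx, cb)
    step_defs[[i]] <- list(
      label = as.character(s$label %||% sprintf("step%d", i)),
      description = as.character(s$description %||% ""),
      proportion = as.numeric(s$proportion %||% NA_real_),
      unit_cost = uc, cost_basis = cb,
      is_intervention = isTRUE(s$is_intervention))
  }
  labs <- vapply(step_defs, `[[`, character(1), "label")
  if (anyDuplicated(labs))
    note("steps: labels must be unique; duplicated: %s",
         paste(unique(labs[duplicated(labs)]), collapse = ", "))

  scen <- raw$scenarios
  if (is.null(scen) || length(scen) == 0L) {
    note("scenarios: at least one scenario is required")
    scen <- list()
  }
  if (is.null(names(scen)) || any(!nzchar(names(scen))))
    note("scenarios: must be a named mapping")
  baseline <- raw$baseline
  if (is.null(baseline)) note("baseline: required (name of the comparator scenario)")
  else if (length(baseline) != 1L)
    note("baseline: exactly one scenario must be designated baseline")
  else if (!baseline %in% names(scen))
    note("baseline: '%s' is not a defined scenario", baseline)
  scenarios <- list()
  for (nm in names(scen)) {
    ov <- scen[[nm]]$overrides %||% list()
    for (st in names(ov)) {
      if (!st %in% labs)
        note("scenarios.%s.overrides.%s: references an undefined step", nm, st)
      bad <- setdiff(names(ov[[st]]),
                     c("proportion", "unit_cost", "cost_basis",
                       "is_intervention", "description"))
      if (length(bad))
        note("scenarios.%s.overrides.%s: unknown field(s) %s", nm, st,
             paste(bad, collapse = ", "))
    }
    scenarios[[nm]] <- list(
      description = as.character(scen[[nm]]$description %||% ""),
      overrides = ov)
  }

  bounds <- raw$bounds %||% list()
  for (i in seq_along(bounds)) {
    b <- bounds[[i]]
    pfx <- sprintf("bounds[%d]", i)
    if (is.null(b$field) ||
        !b$field %in% c("proportion", "unit_cost", "population"))
      note("%s.field: must be proportion, unit_cost or population", pfx)
    if (!identical(b$field, "population") &&
        (is.null(b$step) || !b$step %in% labs))
      note("%s.step: must reference a defined step", pfx)
    if (!is.null(b$scenario) && !b$scenario %in% names(scen))
      note("%s.scenario: '%s' is not a defined scenario", pfx,
           format(b$scenario))
    if (is.null(b$lower) || is.null(b$upper) ||
        as.numeric(b$lower) > as.numeric(b$upper))
      note("%s: requires lower <= upper", pfx)
  }

  report <- raw$report %||% list()
  report <- list(
    rounding = if (is.null(report$rounding)) TRUE else isTRUE(report$rounding),
    format = report$format %||% "table")
  if (!report$format %in% c("table", "csv", "jsonl"))
    note("report.format: must be table, csv or jsonl, got '%s'",
         format(report$format))

  if (length(problems))
    stop("invalid model configuration:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)

  structure(list(schema_version = 1L, currency = currency,
                 population = list(size = pop_size, label = pop_label),
                 baseline = as.character(baseline),
                 steps = step_defs, scenarios = scenarios,
                 bounds = bounds, report = report),
            class = "model_config")
}

#' Write a model_config back to a YAML file
#'
#' [load_config()] of the written file reconstructs an equivalent
#' configuration (round-trip property).
#'
#' @param config A `model_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "model_config"))
  out <- list(schema_version = config$schema_version,
              currency = config$currency,
              population = config$population,
              baseline = config$baseline,
              steps = config$steps,
              scenarios = config$scenarios)
  if (length(config$bounds)) out$bounds <- config$bounds
  out$report <- config$report
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Materialise one configured scenario as a scenario_spec
#'
#' Applies the scenario's sparse overrides to the shared step list.
#'
#' @param config A `model_config`.
#' @param name Scenario name.
#' @return A [scenario_spec()].
#' @export
config_scenario <- function(config, name) {
  stopifnot(inherits(config, "model_config"))
  if (!name %in% names(config$scenarios))
    stop("scenario '", name, "' is not defined in the configuration",
         call. = FALSE)
  ov <- config$scenarios[[name]]$overrides
  steps <- lapply(config$steps, function(s) {
    o <- ov[[s$label]]
    if (!is.null(o)) s[names(o)] <- o
    step_spec(s$label, s$proportion, s$unit_cost,
              cost_basis = s$cost_basis, description = s$description,
              is_intervention = s$is_intervention)
  })
  scenario_spec(name, config$population$size, steps,
                currency = config$currency)
}

#' Materialise every configured scenario
#'
#' @param config A `model_config`.
#' @return A named list of [scenario_spec()] objects, baseline included.
#' @export
config_scenarios <- function(config) {
  stopifnot(inherits(config, "model_config"))
  nms <- names(config$scenarios)
  stats::setNames(lapply(nms, config_scenario, config = config), nms)
}

#' Evaluate every scenario of a configuration and compare against baseline
#'
#' @param config A `model_config` (see [load_config()]).
#' @return An object of class `model_run` with `cascades` (named list of
#'   `cascade_result`, one per scenario), `comparisons` (named list of
#'   `comparison_result`, one per non-baseline scenario) and the originating
#'   `config`.
#' @examples
#' run <- run_model(depression_config())
#' round_for_report(run$cascades$filter1$successes, "count")  # 44156
#' @export
run_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  cascades <- lapply(config_scenarios(config), evaluate_cascade)
  base <- cascades[[config$baseline]]
  others <- setdiff(names(cascades), config$baseline)
  comparisons <- stats::setNames(
    lapply(others, function(nm) compare_scenarios(cascades[[nm]], base)),
    others)
  structure(list(config = config, cascades = cascades,
                 comparisons = comparisons, baseline = config$baseline),
            class = "model_run")
}

#' Run the interval (bounds) analysis declared in a configuration
#'
#' Each entry of the config's `bounds` block is evaluated as a one-way
#' interval on its target scenario (default: the baseline-designated
#' scenario varied against the baseline); entries sharing a `scenario`
#' are grouped into one joint box.
#'
#' @param config A `model_config` with a non-empty `bounds` block.
#' @param n_samples,seed Passed to [bounds_joint()].
#' @return A named list of `bounds_result`, one per target scenario.
#' @export
run_bounds <- function(config, n_samples = 1000, seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  if (!length(config$bounds))
    stop("the configuration declares no bounds intervals", call. = FALSE)
  specs <- config_scenarios(config)
  base <- specs[[config$baseline]]
  targets <- vapply(config$bounds, function(b)
    b$scenario %||% config$baseline, character(1))
  out <- list()
  for (nm in unique(targets)) {
    ivs <- lapply(config$bounds[targets == nm], function(b)
      interval_spec(b$field, b$lower, b$upper,
                    step = b$step, where = b$where %||% "scenario"))
    out[[nm]] <- bounds_joint(specs[[nm]], base, ivs,
                              n_samples = n_samples, seed = seed)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
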