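#' Render a model run as a report
#'
#' Produces a scenario-table report: for every scenario, one row per step
#' (proportion, unit cost, report-rounded persons) followed by the outcome
#' block (cost per exposure, cost per successful outcome, incremental cost,
#' incremental successes, ICER and policy advice versus the baseline).
#' Numbers are exactly [round_for_report()] of the in-memory full-precision
#' values; undefined values render as `"n/a"`.
#'
#' @param run A `model_run` from [run_model()].
#' @param format `"table"` (human-readable text), `"csv"` (stable column
#'   names, RFC-4180-style) or `"jsonl"` (one JSON object per line for
#'   machine consumption).
#' @param round Apply report rounding (default `TRUE`); `FALSE` emits full
#'   precision (csv/jsonl only; the table format always rounds).
#' @param bounds Optional named list of `bounds_result` (from
#'   [run_bounds()]) appended to the report.
#' @param file Optional path; when given the report lines are also written
#'   there.
#' @return Character vector of report lines, invisibly when `file` is
#'   given.
#' @export
render_report <- function(run, format = c("table", "csv", "jsonl"),
                          round = TRUE, bounds = NULL, file = NULL) {
  stopifnot(inherits(run, "model_run"))
  format <- match.arg(format)
  lines <- switch(format,
    table = report_table(run, bounds),
    csv = report_csv(run, round, bounds),
    jsonl = report_jsonl(run, round, bounds))
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

fmt_num <- function(x, round = TRUE, kind = "count") {
  if (is.na(x)) return("n/a")
  if (round) format(round_for_report(x, kind), big.mark = ",", scientific = FALSE)
  else format(x, scientific = FALSE)
}

report_table <- function(run, bounds = NULL) {
  cfg <- run$config
  cur <- cfg$currency
  out <- character(0)
  push <- function(...) out <<- c(out, sprintf(...))
  push("Filter cascade model: %d scenario(s), baseline '%s'",
       length(run$cascades), run$baseline)
  for (nm in names(run$cascades)) {
    cs <- run$cascades[[nm]]
    push("")
    push("== Scenario: %s%s ==", nm,
         if (nm == run$baseline) " (baseline)" else "")
    push("  %-22s %10s %10s %14s", "step", "proportion", "unit cost",
         "persons")
    push("  %-22s %10s %10s %14s", cfg$population$label, "", "",
         fmt_num(cs$population))
    for (i in seq_len(nrow(cs$steps))) {
      r <- cs$steps[i, ]
      push("  %-22s %10.4g %10s %14s", r$label, r$proportion,
           fmt_num(r$unit_cost), fmt_num(r$resulting))
    }
    push("  successes: %s   total cost: %s %s",
         fmt_num(cs$successes), cur, fmt_num(cs$total_cost, kind = "currency"))
    push("  cost/exposure: %s %s   cost/outcome: %s %s", cur,
         fmt_num(cs$cost_per_exposed, kind = "currency"), cur,
         fmt_num(cs$cost_per_success, kind = "currency"))
    if (nm != run$baseline) {
      cp <- run$comparisons[[nm]]
      push("  incremental cost: %s %s   incremental successes: %s   ICER: %s %s",
           cur, fmt_num(cp$incremental_cost, kind = "currency"),
           fmt_num(cp$incremental_successes),
           cur, fmt_num(cp$icer, kind = "currency"))
      push("  policy: %s", cp$quadrant)
      push("  advice: %s", cp$advice)
    }
  }
  if (!is.null(bounds)) {
    for (nm in names(bounds)) {
      b <- bounds[[nm]]
      push("")
      push("== Bounds: %s vs %s (%s) ==", b$scenario_label,
           b$baseline_label, b$method)
      env <- b$envelope
      for (i in seq_len(nrow(env))) {
        if (env$defined[i])
          push("  %-22s [%s, %s]", env$output[i],
               fmt_num(env$lower[i], round = FALSE),
               fmt_num(env$upper[i], round = FALSE))
        else
          push("  %-22s n/a (%s)", env$output[i], env$note[i])
      }
    }
  }
  out
}

# long-format data frame behind the csv report; one row per step per
# scenario, then one row per outcome quantity
report_frame <- function(run, round = TRUE) {
  rnd <- function(x, kind) {
    if (!round) return(x)
    ifelse(is.na(x), NA_real_, round_for_report(x, kind))
  }
  rows <- list()
  add <- function(scenario, section, item, proportion = NA_real_,
                  unit_cost = NA_real_, value = NA_real_, text = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      scenario = scenario, section = section, item = item,
      proportion = proportion, unit_cost = unit_cost, value = value,
      text = text, stringsAsFactors = FALSE)
  }
  for (nm in names(run$cascades)) {
    cs <- run$cascades[[nm]]
    add(nm, "step", "population", value = rnd(cs$population, "count"))
    for (i in seq_len(nrow(cs$steps))) {
      r <- cs$steps[i, ]
      add(nm, "step", r$label, proportion = r$proportion,
          unit_cost = r$unit_cost, value = rnd(r$resulting, "count"))
    }
    add(nm, "outcome", "successes", value = rnd(cs$successes, "count"))
    add(nm, "outcome", "total_cost", value = rnd(cs$total_cost, "currency"))
    add(nm, "outcome", "cost_per_exposed",
        value = rnd(cs$cost_per_exposed, "currency"))
    add(nm, "outcome", "cost_per_success",
        value = rnd(cs$cost_per_success, "currency"))
    if (nm != run$baseline) {
      cp <- run$comparisons[[nm]]
      add(nm, "outcome", "incremental_cost",
          value = rnd(cp$incremental_cost, "currency"))
      add(nm, "outcome", "incremental_successes",
          value = rnd(cp$incremental_successes, "count"))
      add(nm, "outcome", "icer", value = rnd(cp$icer, "currency"))
      add(nm, "outcome", "quadrant", text = cp$quadrant)
      add(nm, "outcome", "advice", text = cp$advice)
    }
  }
  do.call(rbind, rows)
}

report_csv <- function(run, round = TRUE, bounds = NULL) {
  df <- report_frame(run, round)
  if (!is.null(bounds)) {
    for (nm in names(bounds)) {
      env <- bounds[[nm]]$envelope
      bdf <- data.frame(scenario = nm, section = "bounds",
                        item = c(paste0(env$output, "_lower"),
                                 paste0(env$output, "_upper")),
                        proportion = NA_real_, unit_cost = NA_real_,
                        value = c(env$lower, env$upper),
                        text = rep(env$note, 2), stringsAsFactors = FALSE)
      df <- rbind(df, bdf)
    }
  }
  con <- textConnection("csv_lines", "w", local = TRUE)
  utils::write.csv(df, con, row.names = FALSE, na = "n/a")
  close(con)
  csv_lines
}

report_jsonl <- function(run, round = TRUE, bounds = NULL) {
  rnd <- function(x, kind) {
    if (is.null(x) || is.na(x)) return(NULL)
    if (round) round_for_report(x, kind) else x
  }
  lines <- character(0)
  for (nm in names(run$cascades)) {
    cs <- run$cascades[[nm]]
    obj <- list(type = "cascade", scenario = nm,
                baseline = identical(nm, run$baseline),
                population = cs$population,
                steps = lapply(seq_len(nrow(cs$steps)), function(i) {
                  r <- cs$steps[i, ]
                  list(label = r$label, proportion = r$proportion,
                       unit_cost = r$unit_cost,
                       persons = rnd(r$resulting, "count") %||% r$resulting)
                }),
                successes = rnd(cs$successes, "count"),
                total_cost = rnd(cs$total_cost, "currency"),
                cost_per_exposed = rnd(cs$cost_per_exposed, "currency"),
                cost_per_success = rnd(cs$cost_per_success, "currency"))
    lines <- c(lines, jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                                       null = "null"))
  }
  for (nm in names(run$comparisons)) {
    cp <- run$comparisons[[nm]]
    obj <- list(type = "comparison", scenario = nm,
                baseline = cp$baseline_label,
                incremental_cost = rnd(cp$incremental_cost, "currency"),
                incremental_successes = rnd(cp$incremental_successes, "count"),
                icer = rnd(cp$icer, "currency"),
                icer_meaningful = cp$icer_meaningful,
                quadrant = cp$quadrant, advice = cp$advice)
    lines <- c(lines, jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                                       null = "null"))
  }
  if (!is.null(bounds)) {
    for (nm in names(bounds)) {
      b <- bounds[[nm]]
      env <- b$envelope
      obj <- list(type = "bounds", scenario = nm, method = b$method,
                  envelope = lapply(seq_len(nrow(env)), function(i)
                    list(output = env$output[i],
                         lower = if (env$defined[i]) env$lower[i],
                         upper = if (env$defined[i]) env$upper[i],
                         note = env$note[i])))
      lines <- c(lines, jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                                         null = "null"))
    }
  }
  unlist(lines)
}

#' @export
print.model_run <- function(x, ...) {
  cat(report_table(x), sep = "\n")
  invisible(x)
}
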