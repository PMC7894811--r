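#' Define an interval on one model input parameter
#'
#' Intervals express uncertainty in an input as a range; the bounds
#' operations propagate a set of intervals (a parameter box) to lower/upper
#' envelopes on every model output.
#'
#' @param field Which parameter the interval targets: `"proportion"` or
#'   `"unit_cost"` of a step, or `"population"`.
#' @param lower,upper Interval endpoints, `lower <= upper`. Proportion
#'   intervals must lie within `[0, 1]`.
#' @param step Step label the interval targets (required unless
#'   `field = "population"`).
#' @param where Which cascade the parameter belongs to: the varied
#'   `"scenario"` (default) or the `"baseline"` comparator.
#' @return An object of class `interval_spec`.
#' @examples
#' interval_spec("proportion", 0.47, 0.77, step = "detection")
#' @export
interval_spec <- function(field = c("proportion", "unit_cost", "population"),
                          lower, upper, step = NULL,
                          where = c("scenario", "baseline")) {
  field <- match.arg(field)
  where <- match.arg(where)
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (!is.finite(lower) || !is.finite(upper) || lower > upper)
    stop("interval requires finite lower <= upper", call. = FALSE)
  if (field == "proportion" && (lower < 0 || upper > 1))
    stop("proportion intervals must lie within [0, 1]", call. = FALSE)
  if (field != "population" && (is.null(step) || !nzchar(step)))
    stop("a step label is required for '", field, "' intervals",
         call. = FALSE)
  if (field != "proportion" && lower < 0)
    stop(field, " intervals must be non-negative", call. = FALSE)
  structure(list(field = field, step = if (is.null(step)) NA_character_
                 else as.character(step),
                 lower = lower, upper = upper, where = where),
            class = "interval_spec")
}

interval_key <- function(iv) paste(iv$where, iv$step, iv$field, sep = ":")

# set one targeted parameter in a scenario_spec, erroring if it does not exist
set_scenario_param <- function(scenario, iv, value) {
  if (iv$field == "population") {
    scenario$population <- value
    return(scenario)
  }
  i <- match(iv$step, step_labels(scenario))
  if (is.na(i))
    stop(sprintf("interval targets step '%s' which does not exist in scenario '%s'",
                 iv$step, scenario$label), call. = FALSE)
  scenario$steps[[i]][[iv$field]] <- value
  scenario
}

#' Propagate a joint parameter box to bounds on every model output
#'
#' Evaluates the scenario/baseline pair over the box defined by the
#' intervals and reports a lower/upper envelope for each output. Expected
#' counts and total cost are multilinear and monotone non-decreasing in each
#' proportion and unit cost, so their envelope is attained at box corners
#' and corner evaluation is exact; ratio outputs (cost per success, ICER)
#' are ratios of multilinear functions whose extrema need not sit at
#' corners, so the box is additionally sampled with a seeded Latin-hypercube
#' design and the envelope widened to cover the samples
#' (method `"corner+sampled"`).
#'
#' When the incremental successes change sign inside the box the ICER is
#' unbounded; its envelope is then reported as undefined with a diagnostic.
#'
#' @param scenario,baseline [scenario_spec()] objects; `baseline` is the
#'   comparator for the incremental outputs.
#' @param intervals A list of [interval_spec()] objects (a single
#'   `interval_spec` is accepted), at most one per parameter.
#' @param n_samples Number of Latin-hypercube sample points used to refine
#'   the ratio-output envelopes (default 1000).
#' @param corner_limit Maximum number of interval dimensions evaluated by
#'   corner enumeration (default 12, i.e. 4096 corners); beyond it an error
#'   advises one-way analysis.
#' @param seed Integer seed for the sampling design (default 1).
#' @return An object of class `bounds_result`: a data frame `envelope` with
#'   one row per output (`output`, `lower`, `upper`, `defined`, `note`) plus
#'   metadata (`n_corners`, `n_samples`, `method`, `seed`).
#' @examples
#' base <- scenario_spec("base", 1000, list(step_spec("s", 0.5)))
#' alt <- scenario_spec("alt", 1000, list(step_spec("s", 0.8, unit_cost = 1)))
#' bounds_joint(alt, base,
#'   list(interval_spec("proportion", 0.6, 0.9, step = "s")))
#' @export
bounds_joint <- function(scenario, baseline, intervals,
                         n_samples = 1000, corner_limit = 12, seed = 1L) {
  stopifnot(inherits(scenario, "scenario_spec"),
            inherits(baseline, "scenario_spec"))
  if (inherits(intervals, "interval_spec")) intervals <- list(intervals)
  stopifnot(is.list(intervals), length(intervals) >= 1L)
  ok <- vapply(intervals, inherits, logical(1), what = "interval_spec")
  if (!all(ok)) stop("intervals must be interval_spec objects", call. = FALSE)
  keys <- vapply(intervals, interval_key, character(1))
  if (anyDuplicated(keys))
    stop("at most one interval per parameter; duplicated: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "),
         call. = FALSE)
  k <- length(intervals)
  if (k > corner_limit)
    stop(sprintf(paste0(
      "%d intervals would require %s corner evaluations (limit 2^%d); ",
      "raise corner_limit or analyse parameters one at a time with ",
      "bounds_one_way()"), k, format(2^k, big.mark = ","), corner_limit),
      call. = FALSE)

  eval_at <- function(values) {
    sc <- scenario; bs <- baseline
    for (j in seq_len(k)) {
      iv <- intervals[[j]]
      if (iv$where == "scenario") sc <- set_scenario_param(sc, iv, values[j])
      else bs <- set_scenario_param(bs, iv, values[j])
    }
    csc <- evaluate_cascade(sc)
    cbs <- evaluate_cascade(bs)
    cmp <- compare_scenarios(csc, cbs)
    c(successes = csc$successes,
      total_cost = csc$total_cost,
      cost_per_exposed = csc$cost_per_exposed,
      cost_per_success = csc$cost_per_success,
      incremental_cost = cmp$incremental_cost,
      incremental_successes = cmp$incremental_successes,
      icer = cmp$icer)
  }
  # probe for nonexistent targets before enumerating
  lowers <- vapply(intervals, `[[`, numeric(1), "lower")
  uppers <- vapply(intervals, `[[`, numeric(1), "upper")
  eval_at(lowers)

  corners <- as.matrix(expand.grid(lapply(seq_len(k), function(j)
    unique(c(lowers[j], uppers[j])))))
  pts <- corners
  if (n_samples > 0) {
    u <- with_local_seed(seed, lhs::randomLHS(n_samples, k))
    samples <- sweep(sweep(u, 2, uppers - lowers, `*`), 2, lowers, `+`)
    pts <- rbind(corners, samples)
  }
  vals <- t(apply(pts, 1, eval_at))

  outputs <- colnames(vals)
  env <- data.frame(output = outputs, lower = NA_real_, upper = NA_real_,
                    defined = TRUE, note = "", stringsAsFactors = FALSE)
  d_succ <- vals[, "incremental_successes"]
  icer_unbounded <- min(d_succ) < 0 && max(d_succ) > 0
  for (i in seq_along(outputs)) {
    v <- vals[, outputs[i]]
    if (outputs[i] == "icer" && icer_unbounded) {
      env$defined[i] <- FALSE
      env$note[i] <- paste(
        "incremental successes change sign inside the box;",
        "the ICER is unbounded over this parameter range")
      next
    }
    defined <- v[!is.na(v)]
    if (length(defined) == 0L) {
      env$defined[i] <- FALSE
      env$note[i] <- "undefined at every evaluated point"
      next
    }
    env$lower[i] <- min(defined)
    env$upper[i] <- max(defined)
    if (anyNA(v))
      env$note[i] <- "undefined at some evaluated points; envelope covers the defined ones"
  }
  structure(list(envelope = env,
                 scenario_label = scenario$label,
                 baseline_label = baseline$label,
                 n_corners = nrow(corners), n_samples = n_samples,
                 method = "corner+sampled", seed = seed),
            class = "bounds_result")
}

#' One-way sensitivity bounds for a single parameter interval
#'
#' Special case of [bounds_joint()] with one interval; the building block of
#' tornado-style one-at-a-time sensitivity reporting.
#'
#' @inheritParams bounds_joint
#' @param interval A single [interval_spec()].
#' @return A `bounds_result`; see [bounds_joint()].
#' @export
bounds_one_way <- function(scenario, baseline, interval,
                           n_samples = 1000, seed = 1L) {
  stopifnot(inherits(interval, "interval_spec"))
  bounds_joint(scenario, baseline, list(interval),
               n_samples = n_samples, seed = seed)
}

# run code under a fixed RNG state without disturbing the caller's stream
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @export
print.bounds_result <- function(x, ...) {
  cat(sprintf("<bounds_result> '%s' vs '%s' (%s; %d corners + %d samples)\n",
              x$scenario_label, x$baseline_label, x$method,
              x$n_corners, x$n_samples))
  env <- x$envelope
  env$lower <- ifelse(env$defined, format(signif(env$lower, 7)), "n/a")
  env$upper <- ifelse(env$defined, format(signif(env$upper, 7)), "n/a")
  print(env[, c("output", "lower", "upper", "note")], row.names = FALSE)
  invisible(x)
}
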