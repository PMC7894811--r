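#' Cost per participant exposed to the intervention
#'
#' Total scenario cost divided by the expected person-count at the cost
#' basis of the (single) costed step. Under the default post-step basis this
#' equals the unit cost itself. A scenario with no costed step has zero cost
#' and returns 0 by convention. The ratio is undefined (`NA`) when the
#' costed-person denominator is zero with a nonzero cost, or when more than
#' one step carries a cost (no single exposure denominator exists).
#'
#' @param cascade A `cascade_result` from [evaluate_cascade()].
#' @return A currency amount, or `NA_real_` when undefined.
#' @export
cost_per_exposed <- function(cascade) {
  stopifnot(inherits(cascade, "cascade_result"))
  st <- cascade$steps
  costed <- which(st$unit_cost > 0)
  if (length(costed) == 0L) return(0)
  if (length(costed) > 1L) return(NA_real_)
  i <- costed
  denom <- if (st$cost_basis[i] == "post_step") st$resulting[i] else st$entering[i]
  if (denom == 0) {
    if (cascade$total_cost == 0) return(0)
    return(NA_real_)
  }
  cascade$total_cost / denom
}

#' Cost per successful outcome
#'
#' Total scenario cost divided by the expected number of successes, at full
#' precision. Zero-cost scenarios return 0; zero successes with a positive
#' cost is undefined (`NA`).
#'
#' @param cascade A `cascade_result` from [evaluate_cascade()].
#' @return A currency amount, or `NA_real_` when undefined.
#' @export
cost_per_success <- function(cascade) {
  stopifnot(inherits(cascade, "cascade_result"))
  if (cascade$total_cost == 0) return(0)
  if (cascade$successes == 0) return(NA_real_)
  cascade$total_cost / cascade$successes
}

#' Classify a scenario on the cost-effectiveness plane
#'
#' Maps the signs of the incremental cost and incremental successes to the
#' standard cost-effectiveness-plane quadrant and a policy-advice sentence.
#' Ties on one axis follow conventional practice: a free improvement
#' (`delta_cost == 0`, more successes) is dominant, a pure cost
#' (`delta_successes == 0`, more cost) is dominated.
#'
#' @param delta_cost Incremental cost (scenario minus baseline).
#' @param delta_successes Incremental successes (scenario minus baseline).
#' @return A list with `quadrant` (one of `"dominant"`, `"dominated"`,
#'   `"trade_off_more_costly_more_effective"`,
#'   `"trade_off_less_costly_less_effective"`, `"equivalent"`) and `advice`
#'   (a human-readable sentence).
#' @examples
#' classify_policy(4178574, 17204)$quadrant
#' @export
classify_policy <- function(delta_cost, delta_successes) {
  stopifnot(is.finite(delta_cost), is.finite(delta_successes))
  sc <- sign(delta_cost); se <- sign(delta_successes)
  quadrant <-
    if (sc == 0 && se == 0) "equivalent"
    else if (se > 0 && sc <= 0) "dominant"
    else if (se < 0 && sc >= 0) "dominated"
    else if (se == 0 && sc > 0) "dominated"
    else if (se == 0 && sc < 0) "dominant"
    else if (sc > 0) "trade_off_more_costly_more_effective"
    else "trade_off_less_costly_less_effective"
  advice <- switch(quadrant,
    equivalent =
      "The scenario has the same cost and effectiveness as the comparator.",
    dominant = paste(
      "The scenario dominates the comparator: it is no more expensive and",
      "at least as effective (adopt)."),
    dominated = paste(
      "The scenario is dominated by the comparator: it is at least as",
      "expensive and no more effective (reject)."),
    trade_off_more_costly_more_effective = paste(
      "The scenario is both more effective and more expensive than the",
      "comparator; whether the additional successes justify the additional",
      "cost depends on the decision maker's willingness to pay (see ICER)."),
    trade_off_less_costly_less_effective = paste(
      "The scenario is both less expensive and less effective than the",
      "comparator; whether the savings justify the lost successes depends",
      "on the decision maker's willingness to accept (see ICER)."))
  list(quadrant = quadrant, advice = advice)
}

#' Compare a scenario cascade with a baseline cascade
#'
#' Computes the incremental cost and incremental successes (scenario minus
#' baseline) at full precision, the incremental cost-effectiveness ratio
#' (ICER = incremental cost / incremental successes, the cost of one
#' additional success) when the incremental successes are nonzero, and the
#' cost-effectiveness-plane classification. In the dominance quadrants the
#' ICER is still computed but flagged as not meaningful
#' (`icer_meaningful = FALSE`), following standard health-economics
#' practice.
#'
#' @param scenario,baseline `cascade_result` objects from
#'   [evaluate_cascade()]. "Baseline" is whichever scenario the user
#'   designates as the comparator.
#' @return An object of class `comparison_result` with fields
#'   `scenario_label`, `baseline_label`, `incremental_cost`,
#'   `incremental_successes`, `icer` (`NA` when incremental successes are
#'   zero), `icer_meaningful`, `quadrant` and `advice`.
#' @examples
#' base <- evaluate_cascade(scenario_spec("base", 1000,
#'   list(step_spec("s", 0.5))))
#' alt <- evaluate_cascade(scenario_spec("alt", 1000,
#'   list(step_spec("s", 0.8, unit_cost = 1))))
#' compare_scenarios(alt, base)
#' @export
compare_scenarios <- function(scenario, baseline) {
  stopifnot(inherits(scenario, "cascade_result"),
            inherits(baseline, "cascade_result"))
  d_cost <- scenario$total_cost - baseline$total_cost
  d_succ <- scenario$successes - baseline$successes
  cls <- classify_policy(d_cost, d_succ)
  icer <- if (d_succ != 0) d_cost / d_succ else NA_real_
  meaningful <- !is.na(icer) &&
    cls$quadrant %in% c("trade_off_more_costly_more_effective",
                        "trade_off_less_costly_less_effective")
  structure(
    list(scenario_label = scenario$scenario_label,
         baseline_label = baseline$scenario_label,
         currency = scenario$currency,
         incremental_cost = d_cost,
         incremental_successes = d_succ,
         icer = icer,
         icer_meaningful = meaningful,
         quadrant = cls$quadrant,
         advice = cls$advice),
    class = "comparison_result")
}

#' Round a full-precision value for reporting
#'
#' The model carries full floating-point precision internally; reports round
#' person-counts to the nearest integer and currency to the nearest whole
#' unit using half-up rounding (0.5 always rounds away from zero, unlike
#' base R's round-half-even).
#'
#' @param value Finite numeric vector.
#' @param kind `"count"` or `"currency"`; both round to whole units, the
#'   kind is kept for interface clarity.
#' @return Rounded values (integer-valued numeric); `NA` passes through.
#' @examples
#' round_for_report(17203.9, "count")   # 17204
#' round_for_report(94.63, "currency")  # 95
#' @export
round_for_report <- function(value, kind = c("count", "currency")) {
  match.arg(kind)
  if (any(!is.na(value) & !is.finite(value)))
    stop("round_for_report requires finite values", call. = FALSE)
  out <- sign(value) * floor(abs(value) + 0.5)
  out[is.na(value)] <- NA_real_
  out
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> '%s' vs '%s'\n",
              x$scenario_label, x$baseline_label))
  cat(sprintf("  incremental cost:      %s %s\n", x$currency,
              format(round_for_report(x$incremental_cost, "currency"),
                     big.mark = ",")))
  cat(sprintf("  incremental successes: %s\n",
              format(round_for_report(x$incremental_successes, "count"),
                     big.mark = ",")))
  if (is.na(x$icer)) {
    cat("  ICER: n/a (no incremental successes)\n")
  } else {
    cat(sprintf("  ICER: %s %s per additional success%s\n", x$currency,
                format(round_for_report(x$icer, "currency"), big.mark = ","),
                if (x$icer_meaningful) "" else " (not meaningful: dominance)"))
  }
  cat("  ", x$quadrant, "\n", sep = "")
  invisible(x)
}
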