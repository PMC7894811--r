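test_that("per-unit costs reproduce the worked example", {
  cc <- depr_run$cascades
  # under the post-step basis the cost per exposed equals the unit cost
  expect_equal(cc$baseline$cost_per_exposed, 0)
  expect_equal(cc$filter1$cost_per_exposed, 5)
  expect_equal(cc$filter2$cost_per_exposed, 247)
  expect_equal(cc$filter3$cost_per_exposed, 98)
  expect_equal(round_for_report(cc$filter1$cost_per_success, "currency"), 95)
  expect_equal(round_for_report(cc$filter2$cost_per_success, "currency"), 1309)
  expect_equal(round_for_report(cc$filter3$cost_per_success, "currency"), 265)
})

test_that("per-unit costs handle undefined denominators", {
  # zero successes with positive cost: undefined, not a crash
  cs <- evaluate_cascade(toy_scenario(p = c(0.5, 0), cost = c(3, 0)))
  expect_true(is.na(cost_per_success(cs)))
  # zero-cost scenario: 0 by convention
  expect_equal(cost_per_success(evaluate_cascade(toy_scenario())), 0)
  # no single exposure denominator when two steps carry costs
  cs2 <- evaluate_cascade(toy_scenario(p = c(0.5, 0.5), cost = c(1, 2)))
  expect_true(is.na(cost_per_exposed(cs2)))
  # zero costed persons force a zero step cost, so the ratio is 0
  sc <- scenario_spec("z", 10, list(
    step_spec("kill", 0), step_spec("pay", 0.5, unit_cost = 4,
                                    cost_basis = "pre_step")))
  expect_equal(cost_per_exposed(evaluate_cascade(sc)), 0)
  # product identity: cost_per_success * successes = total_cost
  for (seed in c(5, 6, 7)) {
    cs <- evaluate_cascade(random_scenario(seed, cost_range = c(1, 50)))
    expect_equal(cost_per_success(cs) * cs$successes, cs$total_cost,
                 tolerance = 1e-9)
  }
})

test_that("scenario comparisons reproduce the worked example incrementals", {
  cp <- depr_run$comparisons
  expect_equal(round_for_report(cp$filter1$incremental_cost, "currency"),
               4178574)
  expect_equal(round_for_report(cp$filter1$incremental_successes, "count"),
               17204)
  expect_equal(round_for_report(cp$filter1$icer, "currency"), 243)
  expect_equal(round_for_report(cp$filter2$icer, "currency"), 2203)
  expect_equal(round_for_report(cp$filter3$icer, "currency"), 1230)
  # spreadsheet-derived published totals agree within a few dollars
  expect_equal(cp$filter2$incremental_cost, 86938336, tolerance = 5 / 86938336)
  expect_equal(cp$filter3$incremental_cost, 9098352, tolerance = 5 / 9098352)
})

test_that("comparing a cascade with itself is equivalent, not an error", {
  cs <- depr_run$cascades$baseline
  cp <- compare_scenarios(cs, cs)
  expect_equal(cp$incremental_cost, 0)
  expect_equal(cp$incremental_successes, 0)
  expect_true(is.na(cp$icer))
  expect_equal(cp$quadrant, "equivalent")
})

test_that("the quadrant mapping is exhaustive over all nine sign patterns", {
  cases <- expand.grid(dc = c(-1, 0, 1), ds = c(-1, 0, 1))
  expected <- c(
    "-1,-1" = "trade_off_less_costly_less_effective",
    "0,-1" = "dominated", "1,-1" = "dominated",
    "-1,0" = "dominant", "0,0" = "equivalent", "1,0" = "dominated",
    "-1,1" = "dominant", "0,1" = "dominant",
    "1,1" = "trade_off_more_costly_more_effective")
  for (i in seq_len(nrow(cases))) {
    got <- classify_policy(cases$dc[i] * 100, cases$ds[i] * 10)
    key <- paste(cases$dc[i], cases$ds[i], sep = ",")
    expect_equal(got$quadrant, unname(expected[key]), label = key)
    expect_true(nzchar(got$advice))
  }
  # the ICER is flagged as not meaningful outside the trade-off quadrants
  dom <- compare_scenarios(
    evaluate_cascade(toy_scenario("a", p = c(0.9, 0.9))),
    evaluate_cascade(toy_scenario("b", p = c(0.5, 0.5), cost = c(2, 0))))
  expect_equal(dom$quadrant, "dominant")
  expect_false(dom$icer_meaningful)
})

test_that("comparisons are antisymmetric and the ICER is scale-invariant", {
  for (seed in c(11, 12, 13)) {
    a <- evaluate_cascade(random_scenario(seed, cost_range = c(0, 20)))
    b <- evaluate_cascade(random_scenario(seed + 100, cost_range = c(0, 20)))
    ab <- compare_scenarios(a, b); ba <- compare_scenarios(b, a)
    expect_equal(ab$incremental_cost, -ba$incremental_cost)
    expect_equal(ab$incremental_successes, -ba$incremental_successes)
  }
  base <- depr_specs$baseline
  alt <- depr_specs$filter1
  icer0 <- compare_scenarios(evaluate_cascade(alt),
                             evaluate_cascade(base))$icer
  for (k in c(0.5, 2, 10)) {
    bk <- base; bk$population <- k * base$population
    ak <- alt; ak$population <- k * alt$population
    icerk <- compare_scenarios(evaluate_cascade(ak),
                               evaluate_cascade(bk))$icer
    expect_equal(icerk, icer0, tolerance = 1e-12)
  }
})

test_that("report rounding is half-up and rejects non-finite values", {
  expect_equal(round_for_report(0.5, "count"), 1)
  expect_equal(round_for_report(2.5, "currency"), 3)  # not banker's 2
  expect_equal(round_for_report(-2.5, "currency"), -3)
  expect_equal(round_for_report(17203.9, "count"), 17204)
  expect_equal(round_for_report(94.63, "currency"), 95)
  expect_equal(round_for_report(0, "count"), 0)
  expect_true(is.na(round_for_report(NA_real_, "count")))
  expect_error(round_for_report(Inf, "count"), "finite")
})
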