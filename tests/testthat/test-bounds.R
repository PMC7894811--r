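test_that("a detection-rate interval recovers the published outcome range", {
  base <- depr_specs$baseline
  env <- bounds_one_way(
    base, base,
    interval_spec("proportion", 0.47, 0.77, step = "detection"),
    n_samples = 200, seed = 9)$envelope
  succ <- env[env$output == "successes", ]
  expect_equal(round_for_report(c(succ$lower, succ$upper), "count"),
               c(26952, 44156))
  # varied against the fixed baseline, the incremental successes span
  # zero improvement up to the screening scenario's gain
  inc <- env[env$output == "incremental_successes", ]
  expect_equal(round_for_report(c(inc$lower, inc$upper), "count"),
               c(0, 17204))
})

test_that("degenerate intervals collapse to the point evaluation", {
  alt <- depr_specs$filter1
  base <- depr_specs$baseline
  ivs <- list(
    interval_spec("proportion", 0.77, 0.77, step = "detection"),
    interval_spec("unit_cost", 5, 5, step = "detection"))
  env <- bounds_joint(alt, base, ivs, n_samples = 50, seed = 1)$envelope
  cs <- evaluate_cascade(alt)
  cp <- compare_scenarios(cs, evaluate_cascade(base))
  point <- c(successes = cs$successes, total_cost = cs$total_cost,
             incremental_cost = cp$incremental_cost,
             incremental_successes = cp$incremental_successes,
             icer = cp$icer)
  for (nm in names(point)) {
    row <- env[env$output == nm, ]
    expect_equal(row$lower, unname(point[nm]), tolerance = 1e-12)
    expect_equal(row$upper, unname(point[nm]), tolerance = 1e-12)
  }
})

test_that("one-way cost and proportion intervals have closed-form envelopes", {
  alt <- depr_specs$filter1
  base <- depr_specs$baseline
  detected <- 15055403 * 0.089 * 0.81 * 0.77  # post-detection count
  env <- bounds_one_way(alt, base,
                        interval_spec("unit_cost", 2.5, 10,
                                      step = "detection"),
                        n_samples = 100, seed = 2)$envelope
  tc <- env[env$output == "total_cost", ]
  expect_equal(c(tc$lower, tc$upper), detected * c(2.5, 10),
               tolerance = 1e-9)

  # proportion spanning [0, 1] on the final step: annihilator to identity
  env2 <- bounds_one_way(base, base,
                         interval_spec("proportion", 0, 1, step = "outcome"),
                         n_samples = 100, seed = 3)$envelope
  succ <- env2[env2$output == "successes", ]
  entering_final <- 15055403 * 0.089 * 0.81 * 0.47 * 0.28 * 0.51
  expect_equal(succ$lower, 0)
  expect_equal(succ$upper, entering_final, tolerance = 1e-9)
})

test_that("sampled parameter vectors always fall inside the envelope", {
  alt <- depr_specs$filter2
  base <- depr_specs$baseline
  ivs <- list(
    interval_spec("proportion", 0.4, 0.9, step = "reach"),
    interval_spec("unit_cost", 100, 400, step = "reach"),
    interval_spec("proportion", 0.3, 0.6, step = "adherence"))
  b <- bounds_joint(alt, base, ivs, n_samples = 500, seed = 21)
  env <- b$envelope
  lo <- vapply(ivs, `[[`, numeric(1), "lower")
  hi <- vapply(ivs, `[[`, numeric(1), "upper")
  set.seed(77)
  for (rep in 1:2000) {
    v <- stats::runif(3, lo, hi)
    sc <- alt
    for (j in 1:3)
      sc <- filtercascade:::set_scenario_param(sc, ivs[[j]], v[j])
    cs <- evaluate_cascade(sc)
    cp <- compare_scenarios(cs, evaluate_cascade(base))
    vals <- c(successes = cs$successes, total_cost = cs$total_cost,
              cost_per_success = cs$cost_per_success,
              incremental_cost = cp$incremental_cost,
              incremental_successes = cp$incremental_successes,
              icer = cp$icer)
    for (nm in names(vals)) {
      row <- env[env$output == nm, ]
      if (!row$defined || is.na(vals[nm])) next
      expect_true(vals[nm] >= row$lower - 1e-9 * abs(row$lower) &&
                  vals[nm] <= row$upper + 1e-9 * abs(row$upper),
                  label = sprintf("%s within envelope (rep %d)", nm, rep))
    }
  }
})

test_that("shrinking an interval never widens the multilinear envelopes", {
  alt <- depr_specs$filter1
  base <- depr_specs$baseline
  wide <- bounds_joint(alt, base, list(
    interval_spec("proportion", 0.3, 0.9, step = "detection"),
    interval_spec("unit_cost", 0, 20, step = "detection")),
    n_samples = 0, seed = 1)$envelope
  narrow <- bounds_joint(alt, base, list(
    interval_spec("proportion", 0.45, 0.8, step = "detection"),
    interval_spec("unit_cost", 2, 10, step = "detection")),
    n_samples = 0, seed = 1)$envelope
  for (nm in c("successes", "total_cost", "incremental_cost",
               "incremental_successes")) {
    w <- wide[wide$output == nm, ]; nr <- narrow[narrow$output == nm, ]
    expect_true(nr$lower >= w$lower - 1e-12)
    expect_true(nr$upper <= w$upper + 1e-12)
  }
})

test_that("bounds validation errors are informative", {
  base <- depr_specs$baseline
  expect_error(
    bounds_one_way(base, base,
                   interval_spec("proportion", 0.1, 0.2, step = "nope")),
    "does not exist")
  expect_error(interval_spec("proportion", 0.5, 1.2, step = "s"), "\\[0, 1\\]")
  expect_error(interval_spec("proportion", 0.8, 0.2, step = "s"),
               "lower <= upper")
  expect_error(interval_spec("unit_cost", 1, 2), "step label")
  iv <- interval_spec("proportion", 0.1, 0.2, step = "detection")
  expect_error(bounds_joint(base, base, list(iv, iv)),
               "at most one interval")
  ivs <- list(
    interval_spec("proportion", 0.1, 0.2, step = "detection"),
    interval_spec("proportion", 0.1, 0.2, step = "reach"),
    interval_spec("proportion", 0.1, 0.2, step = "adherence"))
  expect_error(bounds_joint(base, base, ivs, corner_limit = 2),
               "one at a time|bounds_one_way")
})

test_that("an ICER whose denominator changes sign is reported undefined", {
  base <- depr_specs$baseline
  alt <- depr_specs$filter1
  # detection below/above the baseline 0.47 flips the sign of the gain
  env <- bounds_one_way(alt, base,
                        interval_spec("proportion", 0.2, 0.77,
                                      step = "detection"),
                        n_samples = 100, seed = 4)$envelope
  icer <- env[env$output == "icer", ]
  expect_false(icer$defined)
  expect_match(icer$note, "sign")
})
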