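test_that("the dual/triple medication mix prices correctly", {
  costs <- base_params()$costs
  # 3:1 mix: 0.75 * 307.24 + 0.25 * 470.45
  expect_equal(annual_medication_cost(costs), 348.0425, tolerance = 1e-10)
  expect_equal(annual_medication_cost(costs, 1.5), 522.06375, tolerance = 1e-10)
  costs$annual_dual_therapy <- costs$annual_triple_therapy <- 100
  expect_equal(annual_medication_cost(costs), 100)
})

test_that("per-state cycle costs follow the strategy rules", {
  costs <- base_params()$costs
  med_only <- strategy("positive", surgery_rate = 0)
  expect_equal(cycle_cost("mild", 1, med_only, costs), 348.0425 + 79.55,
               tolerance = 1e-10)
  expect_equal(cycle_cost("moderate", 3, med_only, costs), 522.06375 + 119.32,
               tolerance = 1e-10)

  all_surgery <- strategy("positive", surgery_rate = 1)
  # entry cycle bills the full trabeculectomy price plus the blended follow-up
  expect_equal(cycle_cost("mild", 0, all_surgery, costs),
               530.97 + 0.8 * 79.55 + 0.2 * (348.0425 + 79.55),
               tolerance = 1e-10)
  expect_equal(cycle_cost("mild", 1, all_surgery, costs),
               0.8 * 79.55 + 0.2 * (348.0425 + 79.55), tolerance = 1e-10)

  trad <- strategy("traditional")
  expect_equal(cycle_cost("mild", 0, trad, costs), 79.55)
  expect_equal(cycle_cost("moderate", 2, trad, costs, first_year = TRUE),
               381.84 + 0.2 * 522.06375, tolerance = 1e-10)
  expect_equal(cycle_cost("severe", 5, trad, costs),
               254.56 + 0.2 * 522.06375, tolerance = 1e-10)

  expect_error(cycle_cost("dead", 1, trad, costs), "contract violation")

  zero <- costs
  for (f in setdiff(names(zero), c("dual_to_triple_ratio",
                                   "dose_multiplier_after_progression",
                                   "surgical_failure_rate"))) zero[[f]] <- 0
  expect_equal(cycle_cost("mild", 0, all_surgery, zero), 0)
  expect_equal(cycle_cost("severe", 1, trad, zero), 0)
})

test_that("discounted strategy totals match the independently computed values", {
  # expected totals computed with a separate direct implementation of the
  # accounting rules (end-of-cycle occupancy, entry tracking, half-weighted
  # entry lump) outside the package
  p <- base_params()
  tr_pos <- run_cohort(p, "positive")
  tr_trad <- run_cohort(p, "traditional")
  expect_equal(run_costing(tr_trad, strategy("traditional"), p)$total_cost_discounted,
               1975.650491, tolerance = 1e-6)
  expect_equal(run_costing(tr_pos, strategy("positive", 0), p)$total_cost_discounted,
               3901.925698, tolerance = 1e-6)
  expect_equal(run_costing(tr_pos, strategy("positive", 0.25), p)$total_cost_discounted,
               3305.259148, tolerance = 1e-6)
  expect_equal(run_costing(tr_pos, strategy("positive", 0.5), p)$total_cost_discounted,
               2708.592597, tolerance = 1e-6)
})

test_that("costs blend linearly in the surgery rate, cycle by cycle", {
  p <- base_params()
  tr <- run_cohort(p, "positive")
  c0 <- run_costing(tr, strategy("positive", 0), p)$per_cycle_cost
  c1 <- run_costing(tr, strategy("positive", 1), p)$per_cycle_cost
  for (s in c(0.2, 0.25, 0.5, 0.8)) {
    cs <- run_costing(tr, strategy("positive", s), p)$per_cycle_cost
    expect_equal(cs, s * c1 + (1 - s) * c0, tolerance = 1e-10)
  }
})

test_that("totals are non-decreasing in the surgery-cost multiplier", {
  p <- base_params()
  tr <- run_cohort(p, "positive")
  tot <- vapply(c(1, 2, 5, 10), function(m)
    run_costing(tr, strategy("positive", 0.5, m), p)$total_cost_discounted, 0)
  expect_true(all(diff(tot) > 0))
  # and flat when nobody is operated on
  tot0 <- vapply(c(1, 5, 10), function(m)
    run_costing(tr, strategy("positive", 0, m), p)$total_cost_discounted, 0)
  expect_equal(diff(tot0), c(0, 0))
})

test_that("each traditional-arm member pays a first-year cost at most once per stage", {
  tr <- run_cohort(base_params(), "traditional")
  # entry fractions are per-member events; no member enters a stage twice
  expect_lte(sum(tr$entrants_moderate), 1)
  expect_lte(sum(tr$entrants_severe), 1)
  expect_lte(sum(tr$entrants_severe), sum(tr$entrants_moderate))
  # entrants never exceed the stage occupancy they join
  expect_true(all(tr$entrants_moderate <= tr$occupancy[-1, "moderate"] + 1e-12))
  expect_true(all(tr$entrants_severe <= tr$occupancy[-1, "severe"] + 1e-12))
})

test_that("the dead state accrues nothing", {
  p <- parameter_preset("stress_high_mortality")
  tr <- run_cohort(p, "positive")
  ct <- run_costing(tr, strategy("positive", 0), p)
  # rebuild the expected per-cycle cost from alive occupancy only
  alive_cost <- vapply(1:10, function(k) {
    e <- tr$occupancy[k + 1, ]
    (e[["mild"]] * (348.0425 + 79.55) +
       (e[["moderate"]] + e[["severe"]]) * (522.06375 + 119.32)) *
      1.035^-(k - 1)
  }, 0)
  expect_equal(ct$per_cycle_cost, alive_cost, tolerance = 1e-9)
})

test_that("contract violations in run_costing are caught", {
  p <- base_params()
  tr <- run_cohort(p, "positive")
  p5 <- ntg_parameters(econ = list(horizon = 5))
  expect_error(run_costing(tr, strategy("positive"), p5), "horizon")
  expect_error(run_costing(tr, strategy("traditional"), p), "arm")
  expect_error(strategy("positive", surgery_rate = 1.2), "\\[0, 1\\]")
  expect_error(strategy("positive", surgery_cost_multiplier = 0.5), ">= 1")
})

test_that("cost inflation compounds annually", {
  expect_identical(inflate_cost(100, 0, 0.035), 100)
  expect_equal(inflate_cost(100, 4, 0.035), 114.752300, tolerance = 1e-6)
  expect_equal(inflate_cost(254.56, 1, 0.035), 263.4696, tolerance = 1e-6)
  expect_error(inflate_cost(100, -1, 0.035), ">= 0")
})
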