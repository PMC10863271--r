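test_that("mortality odds-ratio adjustment works on the odds scale", {
  # oracle: p -> odds, times OR, back to probability
  odds_oracle <- function(p, or) { o <- p / (1 - p) * or; o / (1 + o) }
  expect_equal(adjust_mortality(0.00364, 1.8), odds_oracle(0.00364, 1.8),
               tolerance = 1e-12)
  expect_equal(adjust_mortality(0.00364, 1.8), 0.006532976, tolerance = 1e-6)
  expect_equal(adjust_mortality(0.00518, 1.8), 0.009285521, tolerance = 1e-6)
  expect_equal(adjust_mortality(0.00364, 1.0), 0.00364)
  expect_error(adjust_mortality(0, 1.8), "\\(0, 1\\)")
  expect_error(adjust_mortality(0.1, -1), "> 0")
})

test_that("discount weights follow the annual compounding form", {
  expect_identical(discount_factor(0, 0.035), 1)
  expect_equal(discount_factor(1, 0.035), 1 / 1.035, tolerance = 1e-12)
  expect_equal(discount_factor(0, 0.035, half_cycle = TRUE), 1.035^-0.5,
               tolerance = 1e-12)
  expect_error(discount_factor(1, -0.1), ">= 0")
})

test_that("transition matrices are row-stochastic with the documented structure", {
  p <- base_params()
  for (arm in c("positive", "traditional")) {
    for (k in 0:9) {
      M <- transition_matrix(p, arm, k)
      expect_equal(rowSums(M), c(mild = 1, moderate = 1, severe = 1, dead = 1),
                   tolerance = 1e-12)
      expect_true(all(M >= 0 & M <= 1))
      expect_equal(unname(M["dead", ]), c(0, 0, 0, 1))          # absorbing
      expect_identical(unname(M["mild", "severe"]), 0)          # no skipping
      expect_identical(unname(M[lower.tri(M)]), rep(0, 6))      # no regression
    }
  }
  # treated arm progresses slower than traditional in every alive row
  Mp <- transition_matrix(p, "positive", 0)
  Mt <- transition_matrix(p, "traditional", 0)
  expect_lt(Mp["mild", "moderate"], Mt["mild", "moderate"])
  expect_lt(Mp["moderate", "severe"], Mt["moderate", "severe"])
})

test_that("zero progression and vanishing mortality give the identity on alive states", {
  p <- no_death_params(transitions = list(
    p_mild_to_moderate_positive = 0, p_moderate_to_severe_positive = 0,
    p_mild_to_moderate_traditional = 0, p_moderate_to_severe_traditional = 0))
  M <- transition_matrix(p, "positive", 0)
  expect_equal(unname(M), diag(4), tolerance = 1e-9)
})

test_that("mortality bands are selected by attained age and coverage is enforced", {
  p <- base_params()
  q_early <- transition_matrix(p, "positive", 0)["mild", "dead"]
  q_late <- transition_matrix(p, "positive", 9)["mild", "dead"]
  expect_equal(q_early, adjust_mortality(0.00364, 1.8), tolerance = 1e-12)
  expect_equal(q_late, adjust_mortality(0.00518, 1.8), tolerance = 1e-12)
  expect_error(transition_matrix(p, "positive", 15), "mortality-table coverage")
})

test_that("the cohort trace conserves mass and death is monotone", {
  for (arm in c("positive", "traditional")) {
    tr <- run_cohort(base_params(), arm)
    expect_equal(rowSums(tr$occupancy), rep(1, 11), tolerance = 1e-9)
    expect_true(all(diff(tr$occupancy[, "dead"]) >= 0))
    expect_true(all(tr$occupancy >= 0))
  }
})

test_that("raised mortality odds dominate the unadjusted trace cycle by cycle", {
  p_or1 <- base_params()
  p_or1$mortality$glaucoma_odds_ratio <- 1.0
  dead_or18 <- run_cohort(base_params(), "positive")$occupancy[-1, "dead"]
  dead_or1 <- run_cohort(p_or1, "positive")$occupancy[-1, "dead"]
  expect_true(all(dead_or18 > dead_or1))
})

test_that("discounting reduces QALYs and totals respect their bounds", {
  p <- base_params()
  p0 <- ntg_parameters(econ = list(discount_rate = 0))
  tr <- run_cohort(p, "positive")
  tr0 <- run_cohort(p0, "positive")
  expect_gt(tr0$qalys_discounted, tr$qalys_discounted)
  expect_lte(tr$qalys_discounted, tr$life_years_discounted)
  expect_lte(tr$life_years_discounted, p$econ$horizon)
})

test_that("zero utilities give zero QALYs but unchanged life years", {
  p <- base_params()
  p$utilities <- list(u_mild = 0, u_moderate = 0, u_severe = 0, u_dead = 0)
  validate_parameters(p)
  tr <- run_cohort(p, "positive")
  expect_identical(tr$qalys_discounted, 0)
  expect_gt(tr$life_years_discounted, 0)
})

test_that("the positive arm accrues at least as many QALYs as traditional", {
  expect_gte(run_cohort(base_params(), "positive")$qalys_discounted,
             run_cohort(base_params(), "traditional")$qalys_discounted)
})

test_that("trace export carries occupancy, discount and QALY columns", {
  tr <- run_cohort(base_params(), "positive")
  d <- as.data.frame(tr)
  expect_equal(nrow(d), 10)
  expect_named(d, c("cycle", "mild", "moderate", "severe", "dead",
                    "discount", "qaly"))
  expect_equal(sum(d$qaly), tr$qalys_discounted)
  expect_equal(d$discount, 1.035^-(0:9), tolerance = 1e-12)
})
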