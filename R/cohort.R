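#' Adjust an annual death probability by a mortality odds ratio
#'
#' Glaucoma raises background mortality; the model carries this as an odds
#' ratio applied on the odds scale: the probability is converted to odds,
#' multiplied by `odds_ratio`, and converted back,
#' `p' = o * OR / (1 + o * OR)` with `o = p / (1 - p)`.
#'
#' @param base_p Annual probability of death in the general population,
#'   in `(0, 1)`.
#' @param odds_ratio Mortality odds ratio (> 0); 1 leaves `base_p` unchanged.
#' @return Adjusted annual death probability.
#' @examples
#' adjust_mortality(0.00364, 1.8)   # 0.006533
#' @export
adjust_mortality <- function(base_p, odds_ratio) {
  stopifnot(is.numeric(base_p), is.numeric(odds_ratio))
  if (any(base_p <= 0 | base_p >= 1))
    stop("'base_p' must lie in (0, 1)", call. = FALSE)
  if (any(odds_ratio <= 0)) stop("'odds_ratio' must be > 0", call. = FALSE)
  o <- base_p / (1 - base_p) * odds_ratio
  o / (1 + o)
}

## Background death probability for one model cycle. The band is chosen by
## the age attained at the END of the cycle (start_age + cycle + 1): the
## cohort enters at 64 and its first year of exposure is the risk of dying
## by age 65, which the first printed band (65-69) covers. Ages below the
## first band fall back to the first band; ages beyond the table error.
mortality_for_cycle <- function(params, cycle) {
  age <- params$econ$start_age + cycle + 1
  b <- params$mortality$bands
  i <- which(age >= b$age_from & age <= b$age_to)
  if (length(i) == 0) {
    if (age < min(b$age_from)) i <- which.min(b$age_from)
    else stop("attained age ", age, " is outside the mortality-table coverage",
              call. = FALSE)
  }
  adjust_mortality(b$p_death[i[1]], params$mortality$glaucoma_odds_ratio)
}

#' Per-cycle transition matrix for one strategy arm
#'
#' Builds the 4x4 annual transition matrix over the states
#' mild/moderate/severe/dead for the given cycle. Death competes with
#' progression as an independent additive event: from each alive state the
#' cycle's age-specific death probability `q` (background rate adjusted by
#' the glaucoma odds ratio, see [adjust_mortality()]) is applied, the
#' arm-specific annual progression probability `p` moves survivors one
#' stage forward, and the remaining mass `1 - p - q` stays. Dead is
#' absorbing; no backward or stage-skipping transitions occur within a
#' cycle.
#'
#' @param params An `ntg_params` object.
#' @param arm `"positive"` or `"traditional"`.
#' @param cycle Zero-based cycle index within the horizon.
#' @return A 4x4 row-stochastic matrix with dimnames [NTG_STATES].
#' @export
transition_matrix <- function(params, arm = c("positive", "traditional"),
                              cycle = 0) {
  arm <- match.arg(arm)
  tr <- params$transitions
  p12 <- if (arm == "positive") tr$p_mild_to_moderate_positive else
    tr$p_mild_to_moderate_traditional
  p23 <- if (arm == "positive") tr$p_moderate_to_severe_positive else
    tr$p_moderate_to_severe_traditional
  q <- mortality_for_cycle(params, cycle)
  if (p12 + q > 1 || p23 + q > 1)
    stop("progression and death probabilities exceed 1 in one cycle; ",
         "the annual-cycle competing-event composition is not applicable",
         call. = FALSE)
  m <- rbind(
    c(1 - p12 - q, p12,         0,           q),
    c(0,           1 - p23 - q, p23,         q),
    c(0,           0,           1 - q,       q),
    c(0,           0,           0,           1)
  )
  dimnames(m) <- list(NTG_STATES, NTG_STATES)
  m
}

#' Discount weight for one model cycle
#'
#' Returns `(1 + rate)^-cycle`, or the half-cycle-shifted
#' `(1 + rate)^-(cycle + 0.5)` when `half_cycle = TRUE`. The cohort engine
#' itself uses the unshifted weight and applies its half-cycle correction on
#' state occupancy instead (see [run_cohort()]); the shifted form is
#' provided for users who prefer to put the correction in the discount
#' exponent.
#'
#' @param cycle Zero-based cycle index (vectorised).
#' @param rate Annual discount rate (>= 0).
#' @param half_cycle Shift the exponent by half a cycle?
#' @return Dimensionless discount weight(s).
#' @examples
#' discount_factor(1, 0.035)              # 0.96618
#' discount_factor(0, 0.035, TRUE)        # 0.98294
#' @export
discount_factor <- function(cycle, rate, half_cycle = FALSE) {
  stopifnot(is.numeric(cycle), is.numeric(rate))
  if (any(rate < 0)) stop("'rate' must be >= 0", call. = FALSE)
  (1 + rate)^(-(cycle + if (isTRUE(half_cycle)) 0.5 else 0))
}

#' Run the deterministic Markov cohort for one strategy arm
#'
#' Starts the closed cohort 100% in the mild state at the configured start
#' age and applies the cycle-specific transition matrix for `horizon`
#' annual cycles. Per-cycle quality-adjusted life years are the occupancy
#' (mid-cycle, i.e. the mean of cycle-start and cycle-end state membership,
#' when the half-cycle correction is on; cycle-end otherwise) dotted with
#' the state utilities and weighted by [discount_factor()] at the cycle's
#' start. Life years use the same weights with utility 1 for every alive
#' state.
#'
#' @param params An `ntg_params` object.
#' @param arm `"positive"` or `"traditional"`.
#' @return Object of class `ntg_trace` with components:
#'   \item{occupancy}{`(horizon + 1) x 4` matrix of state fractions, row
#'     `k + 1` holding the distribution after `k` cycles.}
#'   \item{per_cycle_qaly}{Discounted QALY contribution of each cycle.}
#'   \item{qalys_discounted, life_years_discounted}{Totals over the horizon.}
#'   \item{entrants_moderate, entrants_severe}{Fraction of the cohort newly
#'     entering each stage during each cycle (used for first-year costs).}
#' @examples
#' tr <- run_cohort(ntg_parameters(), "positive")
#' tr$qalys_discounted
#' @export
run_cohort <- function(params, arm = c("positive", "traditional")) {
  arm <- match.arg(arm)
  params <- validate_parameters(params)
  h <- params$econ$horizon
  u <- unlist(params$utilities[c("u_mild", "u_moderate", "u_severe", "u_dead")])
  alive <- c(1, 1, 1, 0)
  hcc <- params$econ$half_cycle_correction

  occ <- matrix(0, h + 1, 4, dimnames = list(NULL, NTG_STATES))
  occ[1, ] <- c(1, 0, 0, 0)
  per_cycle_qaly <- per_cycle_ly <- numeric(h)
  ent_mod <- ent_sev <- numeric(h)
  df <- discount_factor(0:(h - 1), params$econ$discount_rate)

  for (k in 0:(h - 1)) {
    M <- transition_matrix(params, arm, k)
    s <- occ[k + 1, ]
    e <- as.vector(s %*% M)
    occ[k + 2, ] <- e
    ent_mod[k + 1] <- s["mild"] * M["mild", "moderate"]
    ent_sev[k + 1] <- s["moderate"] * M["moderate", "severe"]
    w <- if (hcc) (s + e) / 2 else e
    per_cycle_qaly[k + 1] <- sum(w * u) * df[k + 1]
    per_cycle_ly[k + 1] <- sum(w * alive) * df[k + 1]
  }

  structure(list(
    arm = arm,
    occupancy = occ,
    per_cycle_qaly = per_cycle_qaly,
    per_cycle_life_years = per_cycle_ly,
    qalys_discounted = sum(per_cycle_qaly),
    life_years_discounted = sum(per_cycle_ly),
    entrants_moderate = ent_mod,
    entrants_severe = ent_sev,
    discount = df,
    params = params
  ), class = "ntg_trace")
}

#' @export
print.ntg_trace <- function(x, ...) {
  h <- length(x$per_cycle_qaly)
  cat(sprintf("NTG cohort trace: %s arm, %d annual cycles\n", x$arm, h))
  cat(sprintf("  discounted QALYs %.4f, life years %.4f\n",
              x$qalys_discounted, x$life_years_discounted))
  cat(sprintf("  final occupancy: %s\n",
              paste(sprintf("%s %.3f", NTG_STATES, x$occupancy[h + 1, ]),
                    collapse = ", ")))
  invisible(x)
}

#' Tabulate a cohort trace
#'
#' One row per cycle: end-of-cycle state fractions, the discount weight and
#' the discounted per-cycle QALY contribution. Suitable for
#' [utils::write.csv()].
#'
#' @param x An `ntg_trace`.
#' @param ... Unused.
#' @export
as.data.frame.ntg_trace <- function(x, ...) {
  h <- length(x$per_cycle_qaly)
  data.frame(
    cycle = seq_len(h),
    mild = x$occupancy[-1, "mild"],
    moderate = x$occupancy[-1, "moderate"],
    severe = x$occupancy[-1, "severe"],
    dead = x$occupancy[-1, "dead"],
    discount = x$discount,
    qaly = x$per_cycle_qaly,
    row.names = NULL
  )
}

#' @export
plot.ntg_trace <- function(x, ...) {
  h <- nrow(x$occupancy) - 1
  graphics::matplot(0:h, x$occupancy, type = "l", lty = 1, lwd = 2,
                    col = c("#2c7fb8", "#fd8d3c", "#e31a1c", "grey40"),
                    xlab = "cycle (years)", ylab = "fraction of cohort",
                    main = sprintf("Cohort trace (%s arm)", x$arm), ...)
  graphics::legend("right", legend = NTG_STATES, lty = 1, lwd = 2,
                   col = c("#2c7fb8", "#fd8d3c", "#e31a1c", "grey40"),
                   bty = "n")
  invisible(x)
}
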