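#' Define a treatment strategy
#'
#' A strategy is one arm of the comparison plus its surgical settings. The
#' positive arm treats every patient with intensive IOP-lowering medication
#' except for a fraction `surgery_rate` who undergo trabeculectomy at model
#' entry (of whom `costs$surgical_failure_rate` fail and fall back to
#' long-term medication). `surgery_cost_multiplier` inflates the one-time
#' surgery price (used for the 5x / 10x fault-tolerance scenarios). The
#' traditional arm observes mild disease and operates on progression; it
#' ignores the surgery fields.
#'
#' @param arm `"positive"` or `"traditional"`.
#' @param surgery_rate Fraction of positive-arm patients treated by
#'   trabeculectomy at entry, in `[0, 1]`.
#' @param surgery_cost_multiplier Multiplier (>= 1) on the trabeculectomy
#'   price.
#' @return Object of class `ntg_strategy`.
#' @export
strategy <- function(arm = c("positive", "traditional"), surgery_rate = 0,
                     surgery_cost_multiplier = 1) {
  arm <- match.arg(arm)
  if (surgery_rate < 0 || surgery_rate > 1)
    stop("'surgery_rate' must lie in [0, 1]", call. = FALSE)
  if (surgery_cost_multiplier < 1)
    stop("'surgery_cost_multiplier' must be >= 1", call. = FALSE)
  if (arm == "traditional") {
    surgery_rate <- 0
    surgery_cost_multiplier <- 1
  }
  structure(list(arm = arm, surgery_rate = surgery_rate,
                 surgery_cost_multiplier = surgery_cost_multiplier),
            class = "ntg_strategy")
}

#' @export
print.ntg_strategy <- function(x, ...) {
  if (x$arm == "traditional") cat("NTG strategy: traditional management\n")
  else cat(sprintf(
    "NTG strategy: positive treatment, surgery rate %.0f%%, surgery cost x%g\n",
    100 * x$surgery_rate, x$surgery_cost_multiplier))
  invisible(x)
}

#' Expected annual medication cost under the dual/triple therapy mix
#'
#' Patients on IOP-lowering medication receive dual therapy (timolol +
#' latanoprost) or triple therapy in the configured ratio (3:1 by default),
#' so the expected annual cost is `w * dual + (1 - w) * triple` with
#' `w = ratio / (ratio + 1)`, scaled by `dose_multiplier` (1.5 when the
#' escalated dosage after persistent progression applies).
#'
#' @param costs The `costs` component of an `ntg_params` object.
#' @param dose_multiplier Dosage scaling factor (>= 0).
#' @return Expected cost in USD per person-year.
#' @examples
#' annual_medication_cost(ntg_parameters()$costs)        # 348.04
#' annual_medication_cost(ntg_parameters()$costs, 1.5)   # 522.06
#' @export
annual_medication_cost <- function(costs, dose_multiplier = 1) {
  w <- costs$dual_to_triple_ratio / (costs$dual_to_triple_ratio + 1)
  dose_multiplier * (w * costs$annual_dual_therapy +
                       (1 - w) * costs$annual_triple_therapy)
}

#' Per-person cost billed to one state in one cycle
#'
#' Returns the expected direct cost charged to a cohort member occupying
#' `state` at the end of `cycle` under the given strategy.
#'
#' Positive arm, medication path: medication at normal dosage plus the
#' no-progression follow-up while mild; escalated
#' (`dose_multiplier_after_progression`) medication plus the progression
#' follow-up once moderate or severe. Positive arm, surgery path: the full
#' trabeculectomy price (times the strategy multiplier) is billed in cycle
#' 0; in every cycle the successful fraction accrues the no-progression
#' follow-up only, while the failed fraction (`surgical_failure_rate`)
#' accrues normal-dose medication plus the state's follow-up. The two paths
#' are blended by `surgery_rate`.
#'
#' Traditional arm: mild accrues the no-progression follow-up; a cycle
#' entered into the moderate or severe stage is billed the stage's
#' first-year cost (covering trabeculectomy and postoperative care),
#' subsequent years the consecutive-year cost; in addition the surgical
#' failure fraction of stage occupants accrues long-term escalated
#' medication.
#'
#' The dead state accrues nothing and querying it is an error. Note the
#' one-time surgery price returned here is the full billed amount; the
#' accrual weight it receives under the half-cycle correction is applied by
#' [run_costing()].
#'
#' @param state One of `"mild"`, `"moderate"`, `"severe"`.
#' @param cycle Zero-based cycle index.
#' @param strat An `ntg_strategy`.
#' @param costs The `costs` component of an `ntg_params` object.
#' @param progressed Has this member progressed (moderate or severe)?
#'   Defaults to what `state` implies.
#' @param first_year Traditional arm only: is this the member's entry cycle
#'   into the current stage?
#' @return Expected cost in USD for that person-cycle.
#' @export
cycle_cost <- function(state, cycle, strat, costs,
                       progressed = state %in% c("moderate", "severe"),
                       first_year = FALSE) {
  state <- match.arg(state, NTG_STATES)
  if (state == "dead")
    stop("the dead state accrues no cost; querying it is a contract violation",
         call. = FALSE)
  med <- annual_medication_cost(costs)
  fu0 <- costs$followup_no_progression
  fu1 <- costs$followup_progression
  if (strat$arm == "traditional") {
    if (state == "mild") return(fu0)
    stage_cost <- if (first_year) {
      if (state == "moderate") costs$first_year_moderate_B else costs$first_year_severe_B
    } else {
      if (state == "moderate") costs$consecutive_year_moderate_B else
        costs$consecutive_year_severe_B
    }
    return(stage_cost + costs$surgical_failure_rate *
             annual_medication_cost(costs, costs$dose_multiplier_after_progression))
  }
  ## positive arm
  med_path <- if (progressed) {
    annual_medication_cost(costs, costs$dose_multiplier_after_progression) + fu1
  } else med + fu0
  fail <- costs$surgical_failure_rate
  surg_path <- (1 - fail) * fu0 + fail * (med + if (progressed) fu1 else fu0)
  if (cycle == 0)
    surg_path <- surg_path + costs$trabeculectomy * strat$surgery_cost_multiplier
  s <- strat$surgery_rate
  (1 - s) * med_path + s * surg_path
}

#' Accrue discounted strategy costs over a cohort trace
#'
#' Expected per-person cost per cycle is the end-of-cycle occupancy
#' weighted by [cycle_cost()], with the fractions newly entering the
#' moderate and severe stages (tracked by [run_cohort()]) billed the
#' traditional arm's first-year costs. Each cycle is discounted with the
#' same cycle-start weight as the QALYs. Under the half-cycle correction
#' the one-time trabeculectomy outlay at model entry receives weight 1/2,
#' the lump-sum analogue of crediting recurring flows at mid-cycle.
#'
#' @param trace An `ntg_trace` from [run_cohort()].
#' @param strat An `ntg_strategy`; its arm must match the trace's arm.
#' @param params The `ntg_params` used to produce the trace.
#' @return Object of class `ntg_costtrace` with `per_cycle_cost` (USD,
#'   discounted) and `total_cost_discounted`.
#' @examples
#' p <- ntg_parameters()
#' tr <- run_cohort(p, "positive")
#' run_costing(tr, strategy("positive", surgery_rate = 0.5), p)
#' @export
run_costing <- function(trace, strat, params) {
  if (!inherits(trace, "ntg_trace")) stop("'trace' must be an ntg_trace", call. = FALSE)
  if (!inherits(strat, "ntg_strategy")) strat <- do.call(strategy, strat)
  h <- length(trace$per_cycle_qaly)
  if (h != params$econ$horizon)
    stop("trace horizon (", h, ") does not match parameters (",
         params$econ$horizon, ")", call. = FALSE)
  if (trace$arm != strat$arm)
    stop("trace was run for the ", trace$arm, " arm but the strategy is ",
         strat$arm, call. = FALSE)
  costs <- params$costs
  df <- trace$discount
  hcc <- params$econ$half_cycle_correction
  per_cycle <- numeric(h)

  for (k in 0:(h - 1)) {
    e <- trace$occupancy[k + 2, ]
    if (strat$arm == "traditional") {
      em <- trace$entrants_moderate[k + 1]
      es <- trace$entrants_severe[k + 1]
      ck <- e["mild"] * cycle_cost("mild", k, strat, costs) +
        em * cycle_cost("moderate", k, strat, costs, first_year = TRUE) +
        (e["moderate"] - em) * cycle_cost("moderate", k, strat, costs) +
        es * cycle_cost("severe", k, strat, costs, first_year = TRUE) +
        (e["severe"] - es) * cycle_cost("severe", k, strat, costs)
    } else {
      ## recurring components only; the entry lump is handled below
      recur <- function(state) cycle_cost(state, cycle = 1, strat, costs)
      ck <- e["mild"] * recur("mild") + e["moderate"] * recur("moderate") +
        e["severe"] * recur("severe")
    }
    per_cycle[k + 1] <- ck * df[k + 1]
  }
  if (strat$arm == "positive" && strat$surgery_rate > 0) {
    lump <- strat$surgery_rate * costs$trabeculectomy *
      strat$surgery_cost_multiplier * (if (hcc) 0.5 else 1)
    per_cycle[1] <- per_cycle[1] + lump * df[1]
  }
  structure(list(
    arm = strat$arm, strategy = strat,
    per_cycle_cost = unname(per_cycle),
    total_cost_discounted = sum(per_cycle)
  ), class = "ntg_costtrace")
}

#' @export
print.ntg_costtrace <- function(x, ...) {
  cat(sprintf("NTG cost trace (%s arm): discounted total $%.2f over %d cycles\n",
              x$arm, x$total_cost_discounted, length(x$per_cycle_cost)))
  invisible(x)
}

#' Inflate a cost forward in time
#'
#' Simple compound inflation, `cost * (1 + rate)^years`, used to bring
#' historical unit costs up to the price year of the analysis.
#'
#' @param cost Cost in USD.
#' @param years Number of years to inflate over (>= 0).
#' @param rate Annual inflation rate.
#' @return Inflated cost in USD.
#' @examples
#' inflate_cost(100, 4, 0.035)   # 114.75
#' @export
inflate_cost <- function(cost, years, rate = 0.035) {
  stopifnot(is.numeric(cost), is.numeric(years), is.numeric(rate))
  if (any(years < 0)) stop("'years' must be >= 0", call. = FALSE)
  cost * (1 + rate)^years
}
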