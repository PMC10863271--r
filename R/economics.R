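#' Incremental cost-utility ratio
#'
#' `ICUR = delta_cost / delta_qaly`, the extra cost per additional
#' quality-adjusted life year of the more effective strategy. Dominance is
#' reported as a label instead of an uninterpretable negative ratio: a
#' strategy that gains QALYs while saving money is `"dominant"`, one that
#' costs more while losing QALYs is `"dominated"`. A zero QALY increment
#' has no defined ratio and raises an error rather than silently dividing.
#'
#' @param delta_cost Incremental cost in USD.
#' @param delta_qaly Incremental QALYs.
#' @return The ratio in USD per QALY, or the character label `"dominant"` /
#'   `"dominated"`.
#' @examples
#' icur(1911.59, 0.15)   # 12743.93
#' icur(-100, 0.15)      # "dominant"
#' @export
icur <- function(delta_cost, delta_qaly) {
  stopifnot(is.numeric(delta_cost), is.numeric(delta_qaly),
            length(delta_cost) == 1, length(delta_qaly) == 1)
  if (delta_qaly == 0)
    stop("ICUR is undefined for a zero QALY increment", call. = FALSE)
  if (delta_qaly > 0 && delta_cost < 0) return("dominant")
  if (delta_qaly < 0 && delta_cost > 0) return("dominated")
  delta_cost / delta_qaly
}

#' Classify an ICUR against GDP-based willingness-to-pay thresholds
#'
#' The decision rule compares the ratio with one and three times GDP per
#' capita: below 1x GDP the favoured strategy is worthwhile; between 1x and
#' 3x GDP it is acceptable for clinical application; above 3x GDP it is not
#' acceptable. Dominance labels pass through as `"dominant"` /
#' `"dominated"`.
#'
#' @param icur_value Numeric ICUR in USD/QALY, or a dominance label from
#'   [icur()].
#' @param gdp GDP per capita in USD (default the model's 2023 value).
#' @return One of `"worthwhile_1xGDP"`, `"acceptable_3xGDP"`,
#'   `"not_acceptable"`, `"dominant"`, `"dominated"`.
#' @examples
#' wtp_classify(4851.93, 12692.90)    # worthwhile_1xGDP
#' wtp_classify(12743.93, 12692.90)   # acceptable_3xGDP
#' @export
wtp_classify <- function(icur_value, gdp = 12692.90) {
  if (is.character(icur_value)) {
    if (icur_value %in% c("dominant", "dominated")) return(icur_value)
    stop("unrecognised ICUR label '", icur_value, "'", call. = FALSE)
  }
  stopifnot(is.numeric(icur_value), length(icur_value) == 1, gdp > 0)
  if (icur_value < gdp) "worthwhile_1xGDP"
  else if (icur_value < 3 * gdp) "acceptable_3xGDP"
  else "not_acceptable"
}

#' Fit the two-arm cost-utility model
#'
#' The central model-fitting function: runs the deterministic Markov cohort
#' ([run_cohort()]) and cost accrual ([run_costing()]) for the positive
#' strategy and for traditional management under a common parameter set,
#' and assembles the incremental comparison.
#'
#' @param params An `ntg_params` object (default [ntg_parameters()]).
#' @param positive An `ntg_strategy` for the positive arm, or a numeric
#'   surgery rate as shorthand (`compare_strategies(p, 0.5)`).
#' @return Object of class `ntg_cua` with per-arm traces and cost traces,
#'   per-person discounted costs and QALYs, incremental cost and QALYs, the
#'   ICUR (USD/QALY, or a dominance label) and its willingness-to-pay
#'   classification. Methods: `print`, `summary`, `coef`, `plot`,
#'   `simulate`.
#' @examples
#' fit <- compare_strategies(ntg_parameters(), strategy("positive", 0.5))
#' fit
#' coef(fit)
#' @export
compare_strategies <- function(params = ntg_parameters(),
                               positive = strategy("positive")) {
  params <- validate_parameters(params)
  if (is.numeric(positive)) positive <- strategy("positive", surgery_rate = positive)
  if (!inherits(positive, "ntg_strategy") || positive$arm != "positive")
    stop("'positive' must be an ntg_strategy with arm = \"positive\"",
         call. = FALSE)
  trad_strat <- strategy("traditional")

  tr_pos <- run_cohort(params, "positive")
  tr_trad <- run_cohort(params, "traditional")
  co_pos <- run_costing(tr_pos, positive, params)
  co_trad <- run_costing(tr_trad, trad_strat, params)

  delta_cost <- co_pos$total_cost_discounted - co_trad$total_cost_discounted
  delta_qaly <- tr_pos$qalys_discounted - tr_trad$qalys_discounted
  ic <- if (delta_qaly == 0) NA_real_ else icur(delta_cost, delta_qaly)
  wtp <- if (delta_qaly == 0) "undefined" else
    wtp_classify(ic, params$econ$gdp_per_capita)

  structure(list(
    params = params,
    strategy_positive = positive,
    trace_positive = tr_pos, trace_traditional = tr_trad,
    costs_positive = co_pos, costs_traditional = co_trad,
    cost_positive = co_pos$total_cost_discounted,
    cost_traditional = co_trad$total_cost_discounted,
    qaly_positive = tr_pos$qalys_discounted,
    qaly_traditional = tr_trad$qalys_discounted,
    delta_cost = delta_cost,
    delta_qaly = delta_qaly,
    icur = ic,
    wtp_class = wtp,
    gdp_per_capita = params$econ$gdp_per_capita
  ), class = "ntg_cua")
}

#' @export
print.ntg_cua <- function(x, digits = 2, ...) {
  s <- x$strategy_positive
  cat("Cost-utility comparison: positive vs traditional NTG treatment\n")
  cat(sprintf("  positive arm: surgery rate %.0f%%%s\n", 100 * s$surgery_rate,
              if (s$surgery_cost_multiplier != 1)
                sprintf(", surgery cost x%g", s$surgery_cost_multiplier) else ""))
  cat(sprintf("  cost/person:  positive $%.*f, traditional $%.*f\n",
              digits, x$cost_positive, digits, x$cost_traditional))
  cat(sprintf("  QALYs/person: positive %.*f, traditional %.*f\n",
              digits, x$qaly_positive, digits, x$qaly_traditional))
  cat(sprintf("  incremental:  $%.*f for %.*f QALYs\n",
              digits, x$delta_cost, digits + 2, x$delta_qaly))
  if (is.character(x$icur)) cat("  ICUR: ", x$icur, "\n", sep = "")
  else if (is.na(x$icur)) cat("  ICUR: undefined (zero QALY increment)\n")
  else cat(sprintf("  ICUR: $%.*f per QALY (%s at WTP $%.2f = 1x GDP)\n",
                   digits, x$icur, x$wtp_class, x$gdp_per_capita))
  invisible(x)
}

#' @export
summary.ntg_cua <- function(object, ...) {
  structure(list(fit = object,
                 trace_positive = as.data.frame(object$trace_positive),
                 trace_traditional = as.data.frame(object$trace_traditional)),
            class = "summary.ntg_cua")
}

#' @export
print.summary.ntg_cua <- function(x, ...) {
  print(x$fit)
  cat("\nPositive-arm trace (end-of-cycle fractions):\n")
  print(round(x$trace_positive, 4))
  cat("\nTraditional-arm trace:\n")
  print(round(x$trace_traditional, 4))
  invisible(x)
}

#' @export
coef.ntg_cua <- function(object, ...) {
  c(cost_positive = object$cost_positive,
    cost_traditional = object$cost_traditional,
    qaly_positive = object$qaly_positive,
    qaly_traditional = object$qaly_traditional,
    delta_cost = object$delta_cost,
    delta_qaly = object$delta_qaly,
    icur = if (is.numeric(object$icur)) object$icur else NA_real_)
}

#' @export
plot.ntg_cua <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(x$trace_positive)
  plot(x$trace_traditional)
  invisible(x)
}

#' Base-case comparison table across surgery-rate strategies
#'
#' Formats one row pair per strategy in the conventional CUA layout:
#' average per-person cost, incremental cost, average QALYs, incremental
#' QALYs, and ICUR, each rounded to two decimals. With the default
#' `surgery_rates` this reproduces the structure of the base-case results
#' table (all-medication, 25% and 50% surgery strategies against the same
#' traditional comparator).
#'
#' @param params An `ntg_params` object.
#' @param surgery_rates Numeric vector of positive-arm surgery rates.
#' @param surgery_cost_multiplier Multiplier applied to all strategies.
#' @return A data frame with one row per strategy plus the shared
#'   traditional comparator values.
#' @export
ce_table <- function(params = ntg_parameters(),
                     surgery_rates = c(0, 0.25, 0.5),
                     surgery_cost_multiplier = 1) {
  rows <- lapply(surgery_rates, function(s) {
    fit <- compare_strategies(params,
                              strategy("positive", s, surgery_cost_multiplier))
    data.frame(
      strategy = if (s == 0) "all medication" else sprintf("%.0f%% surgery", 100 * s),
      cost_positive = round(fit$cost_positive, 2),
      cost_traditional = round(fit$cost_traditional, 2),
      incremental_cost = round(fit$delta_cost, 2),
      qaly_positive = round(fit$qaly_positive, 2),
      qaly_traditional = round(fit$qaly_traditional, 2),
      incremental_qaly = round(fit$delta_qaly, 2),
      icur = if (is.numeric(fit$icur)) round(fit$icur, 2) else NA_real_,
      wtp_class = fit$wtp_class,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
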