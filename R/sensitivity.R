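## ---- one-way (tornado) sensitivity analysis ----

## The named levers a one-way plan may perturb. Compound levers scale
## several unit costs together; "surgery_rate" is set to absolute levels.
one_way_levers <- function() c(
  "surgery_rate",
  "p_mild_to_moderate_positive", "p_moderate_to_severe_positive",
  "p_mild_to_moderate_traditional", "p_moderate_to_severe_traditional",
  "eye_drops", "trabeculectomy", "follow_up",
  "u_mild", "u_moderate", "u_severe"
)

apply_lever <- function(params, strat, lever, value, how) {
  mul <- function(x) if (how == "set") value else x * value
  switch(lever,
    surgery_rate = {
      strat <- strategy("positive", surgery_rate = mul(strat$surgery_rate),
                        surgery_cost_multiplier = strat$surgery_cost_multiplier)
    },
    eye_drops = {
      params$costs$annual_dual_therapy <- mul(params$costs$annual_dual_therapy)
      params$costs$annual_triple_therapy <- mul(params$costs$annual_triple_therapy)
    },
    trabeculectomy = {
      params$costs$trabeculectomy <- mul(params$costs$trabeculectomy)
    },
    follow_up = {
      params$costs$followup_no_progression <- mul(params$costs$followup_no_progression)
      params$costs$followup_progression <- mul(params$costs$followup_progression)
    },
    p_mild_to_moderate_positive = ,
    p_moderate_to_severe_positive = ,
    p_mild_to_moderate_traditional = ,
    p_moderate_to_severe_traditional = {
      params$transitions[[lever]] <- mul(params$transitions[[lever]])
    },
    u_mild = , u_moderate = , u_severe = {
      params$utilities[[lever]] <- mul(params$utilities[[lever]])
    },
    stop("unknown one-way lever '", lever, "'; available: ",
         paste(one_way_levers(), collapse = ", "), call. = FALSE)
  )
  list(params = validate_parameters(params), strat = strat)
}

#' Default one-way sensitivity plan
#'
#' The scenario set of the base analysis at a 50% surgery rate: surgery
#' uptake varied between 25% and 50% (absolute levels), the positive-arm
#' transition probabilities by +/-50%, and the eye-drop, trabeculectomy and
#' follow-up unit costs by +/-20%.
#'
#' @return Data frame with columns `parameter`, `low`, `high`, `how`
#'   (`"multiply"` or `"set"`), suitable for [one_way()].
#' @export
default_one_way_plan <- function() {
  data.frame(
    parameter = c("surgery_rate",
                  "p_mild_to_moderate_positive", "p_moderate_to_severe_positive",
                  "eye_drops", "trabeculectomy", "follow_up"),
    low  = c(0.25, 0.5, 0.5, 0.8, 0.8, 0.8),
    high = c(0.50, 1.5, 1.5, 1.2, 1.2, 1.2),
    how  = c("set", rep("multiply", 5)),
    stringsAsFactors = FALSE
  )
}

#' One-way deterministic sensitivity analysis
#'
#' Re-fits [compare_strategies()] twice per plan row, with exactly one
#' lever moved to its low and high setting, and records the resulting
#' ICURs and incremental costs. The base case is left untouched. Rows are
#' returned sorted by ICUR spread (descending, stable on ties), ready for a
#' tornado display via the `plot` method.
#'
#' @param params Base `ntg_params`.
#' @param strat Base positive-arm `ntg_strategy` (default 50% surgery).
#' @param plan Data frame as produced by [default_one_way_plan()].
#' @return Object of classes `ntg_tornado` and `data.frame`: one row per
#'   lever with `low`/`high` settings, `icur_low`, `icur_high`, `spread`
#'   (absolute ICUR difference), and incremental-cost analogues
#'   `dcost_low`, `dcost_high`, `dcost_spread`. The base-case fit is
#'   attached as attribute `"base"`.
#' @examples
#' tor <- one_way(ntg_parameters(), strategy("positive", 0.5))
#' tor$parameter[1]
#' @export
one_way <- function(params = ntg_parameters(),
                    strat = strategy("positive", 0.5),
                    plan = default_one_way_plan()) {
  stopifnot(is.data.frame(plan),
            all(c("parameter", "low", "high") %in% names(plan)))
  if (is.null(plan$how)) plan$how <- "multiply"
  base <- compare_strategies(params, strat)
  one <- function(lever, value, how) {
    z <- apply_lever(params, strat, lever, value, how)
    compare_strategies(z$params, z$strat)
  }
  rows <- lapply(seq_len(nrow(plan)), function(i) {
    lo <- one(plan$parameter[i], plan$low[i], plan$how[i])
    hi <- one(plan$parameter[i], plan$high[i], plan$how[i])
    num <- function(x) if (is.numeric(x$icur)) x$icur else NA_real_
    data.frame(
      parameter = plan$parameter[i],
      low = plan$low[i], high = plan$high[i], how = plan$how[i],
      icur_low = num(lo), icur_high = num(hi),
      spread = abs(num(hi) - num(lo)),
      dcost_low = lo$delta_cost, dcost_high = hi$delta_cost,
      dcost_spread = abs(hi$delta_cost - lo$delta_cost),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$spread), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "base") <- base
  class(out) <- c("ntg_tornado", "data.frame")
  out
}

#' Tornado plot of one-way sensitivity results
#'
#' Horizontal bars from the base-case ICUR to each lever's low and high
#' ICUR, widest spread on top.
#'
#' @param x An `ntg_tornado` from [one_way()].
#' @param ... Further arguments passed to [graphics::barplot()].
#' @export
plot.ntg_tornado <- function(x, ...) {
  if (nrow(x) == 0) stop("empty tornado: no one-way rows to plot", call. = FALSE)
  base <- attr(x, "base")$icur
  d <- x[nrow(x):1, ]   # widest at the top of the barplot
  lo <- pmin(d$icur_low, d$icur_high) - base
  hi <- pmax(d$icur_low, d$icur_high) - base
  ylim <- range(0, lo, hi)
  mid <- graphics::barplot(rbind(lo, hi), beside = FALSE, horiz = TRUE,
                           names.arg = d$parameter, las = 1,
                           col = c("#9ecae1", "#3182bd"),
                           xlim = ylim + base, offset = base,
                           xlab = "ICUR (USD/QALY)",
                           main = "One-way sensitivity (tornado)", ...)
  graphics::abline(v = base, lwd = 2)
  invisible(x)
}

## ---- probabilistic sensitivity analysis ----

#' Specify a probabilistic sensitivity analysis
#'
#' Parameter uncertainty is propagated by Monte Carlo: transition
#' probabilities and utilities are drawn from Beta distributions and unit
#' costs from Gamma distributions, each moment-matched to mean equal to the
#' base-case value and standard deviation `sd_fraction` times the mean
#' (10% by default, the assumption used when source SDs are unavailable).
#' Mortality rates and the mortality odds ratio are held fixed.
#'
#' @param n_samples Number of Monte Carlo draws (>= 1).
#' @param sd_fraction SD as a fraction of the mean (>= 0; 0 collapses every
#'   distribution to its mean).
#' @return Object of class `ntg_psa_spec`.
#' @export
psa_spec <- function(n_samples = 10000, sd_fraction = 0.10) {
  stopifnot(n_samples >= 1, sd_fraction >= 0)
  structure(list(n_samples = as.integer(n_samples), sd_fraction = sd_fraction),
            class = "ntg_psa_spec")
}

psa_columns <- function() c(
  "p_mild_to_moderate_positive", "p_moderate_to_severe_positive",
  "p_mild_to_moderate_traditional", "p_moderate_to_severe_traditional",
  "u_mild", "u_moderate", "u_severe",
  "annual_dual_therapy", "annual_triple_therapy", "trabeculectomy",
  "followup_no_progression", "followup_progression",
  "first_year_moderate_B", "first_year_severe_B",
  "consecutive_year_moderate_B", "consecutive_year_severe_B"
)

psa_base_values <- function(base) {
  tr <- base$transitions; u <- base$utilities; cc <- base$costs
  c(tr$p_mild_to_moderate_positive, tr$p_moderate_to_severe_positive,
    tr$p_mild_to_moderate_traditional, tr$p_moderate_to_severe_traditional,
    u$u_mild, u$u_moderate, u$u_severe,
    cc$annual_dual_therapy, cc$annual_triple_therapy, cc$trabeculectomy,
    cc$followup_no_progression, cc$followup_progression,
    cc$first_year_moderate_B, cc$first_year_severe_B,
    cc$consecutive_year_moderate_B, cc$consecutive_year_severe_B)
}

## n x 16 matrix of parameter draws; probabilities/utilities Beta,
## costs Gamma, both moment-matched to (mean, sd_fraction * mean).
psa_draw_matrix <- function(base, spec, n) {
  means <- psa_base_values(base)
  f <- spec$sd_fraction
  kind <- c(rep("beta", 7), rep("gamma", 9))
  draws <- matrix(0, n, length(means), dimnames = list(NULL, psa_columns()))
  for (j in seq_along(means)) {
    m <- means[j]
    if (f == 0 || m == 0) { draws[, j] <- m; next }
    s <- f * m
    if (kind[j] == "beta") {
      v <- m * (1 - m) / s^2 - 1
      if (v <= 0) stop("Beta moment matching failed for '", psa_columns()[j],
                       "': variance too large", call. = FALSE)
      draws[, j] <- stats::rbeta(n, m * v, (1 - m) * v)
    } else {
      shape <- 1 / f^2
      draws[, j] <- stats::rgamma(n, shape = shape, rate = shape / m)
    }
  }
  draws
}

#' Draw one perturbed parameter set for probabilistic sensitivity analysis
#'
#' Samples a single complete `ntg_params` from the PSA distributions (see
#' [psa_spec()]) using the current RNG state. Per-draw utility ordering
#' (mild >= moderate >= severe) is not enforced; [run_psa()] counts and
#' reports violations instead.
#'
#' @param base Base-case `ntg_params`.
#' @param spec An `ntg_psa_spec`.
#' @return A (not re-validated) `ntg_params` with the drawn values.
#' @export
draw_parameters <- function(base, spec = psa_spec()) {
  psa_row_parameters(base, psa_draw_matrix(base, spec, 1)[1, ])
}

#' Rebuild a full parameter set from one stored PSA draw
#'
#' Inverse of the draw bookkeeping: takes one row of the `draws` matrix
#' stored in an [run_psa()] result and plugs it into the base-case
#' parameter set, so any individual Monte Carlo scenario can be re-run
#' deterministically through [compare_strategies()].
#'
#' @param base Base-case `ntg_params`.
#' @param row Named numeric vector (one row of the PSA draw matrix).
#' @return An `ntg_params` (not re-validated: draws may violate the
#'   utility-ordering invariant by design).
#' @export
psa_row_parameters <- function(base, row) {
  p <- base
  for (nm in c("p_mild_to_moderate_positive", "p_moderate_to_severe_positive",
               "p_mild_to_moderate_traditional", "p_moderate_to_severe_traditional"))
    p$transitions[[nm]] <- unname(row[nm])
  for (nm in c("u_mild", "u_moderate", "u_severe"))
    p$utilities[[nm]] <- unname(row[nm])
  for (nm in c("annual_dual_therapy", "annual_triple_therapy", "trabeculectomy",
               "followup_no_progression", "followup_progression",
               "first_year_moderate_B", "first_year_severe_B",
               "consecutive_year_moderate_B", "consecutive_year_severe_B"))
    p$costs[[nm]] <- unname(row[nm])
  class(p) <- "ntg_params"
  p
}

## Vectorised evaluation of both arms for every draw. Mirrors run_cohort /
## run_costing exactly (the agreement is enforced by a test), but carries
## all n draws through the 10-cycle recursion as vectors.
psa_evaluate <- function(draws, base, strat) {
  n <- nrow(draws)
  h <- base$econ$horizon
  df <- discount_factor(0:(h - 1), base$econ$discount_rate)
  hcc <- base$econ$half_cycle_correction
  qcyc <- vapply(0:(h - 1), function(k) mortality_for_cycle(base, k), 0)
  w <- base$costs$dual_to_triple_ratio / (base$costs$dual_to_triple_ratio + 1)
  med <- w * draws[, "annual_dual_therapy"] + (1 - w) * draws[, "annual_triple_therapy"]
  dm <- base$costs$dose_multiplier_after_progression
  fr <- base$costs$surgical_failure_rate
  fu0 <- draws[, "followup_no_progression"]
  fu1 <- draws[, "followup_progression"]

  run_arm <- function(arm) {
    if (arm == "positive") {
      p12 <- draws[, "p_mild_to_moderate_positive"]
      p23 <- draws[, "p_moderate_to_severe_positive"]
    } else {
      p12 <- draws[, "p_mild_to_moderate_traditional"]
      p23 <- draws[, "p_moderate_to_severe_traditional"]
    }
    mild <- rep(1, n); mod <- sev <- numeric(n)
    qaly <- cost <- numeric(n)
    if (arm == "positive" && strat$surgery_rate > 0) {
      cost <- cost + strat$surgery_rate * draws[, "trabeculectomy"] *
        strat$surgery_cost_multiplier * (if (hcc) 0.5 else 1) * df[1]
    }
    for (k in seq_len(h)) {
      q <- qcyc[k]
      em <- mild * p12
      es <- mod * p23
      mild_e <- mild * (1 - p12 - q)
      mod_e <- em + mod * (1 - p23 - q)
      sev_e <- es + sev * (1 - q)
      um <- if (hcc) (mild + mild_e) / 2 else mild_e
      umo <- if (hcc) (mod + mod_e) / 2 else mod_e
      us <- if (hcc) (sev + sev_e) / 2 else sev_e
      qaly <- qaly + (um * draws[, "u_mild"] + umo * draws[, "u_moderate"] +
                        us * draws[, "u_severe"]) * df[k]
      if (arm == "positive") {
        med_path <- mild_e * (med + fu0) + (mod_e + sev_e) * (dm * med + fu1)
        s <- strat$surgery_rate
        if (s > 0) {
          succ <- fu0 * (mild_e + mod_e + sev_e)
          failp <- mild_e * (med + fu0) + (mod_e + sev_e) * (med + fu1)
          cost <- cost + ((1 - s) * med_path +
                            s * ((1 - fr) * succ + fr * failp)) * df[k]
        } else cost <- cost + med_path * df[k]
      } else {
        ck <- mild_e * fu0 +
          em * draws[, "first_year_moderate_B"] +
          (mod_e - em) * draws[, "consecutive_year_moderate_B"] +
          es * draws[, "first_year_severe_B"] +
          (sev_e - es) * draws[, "consecutive_year_severe_B"] +
          fr * (mod_e + sev_e) * dm * med
        cost <- cost + ck * df[k]
      }
      mild <- mild_e; mod <- mod_e; sev <- sev_e
    }
    list(cost = cost, qaly = qaly)
  }
  pos <- run_arm("positive")
  trad <- run_arm("traditional")
  data.frame(cost_positive = pos$cost, cost_traditional = trad$cost,
             qaly_positive = pos$qaly, qaly_traditional = trad$qaly)
}

#' Run the probabilistic sensitivity analysis
#'
#' Draws `spec$n_samples` parameter sets (see [psa_spec()]) and evaluates
#' the full two-arm model for each, through a vectorised engine that
#' reproduces [compare_strategies()] draw for draw. The headline statistic
#' is the ICUR of means: mean incremental cost over mean incremental QALYs
#' across draws (not the mean of per-draw ratios, which is unstable when
#' QALY increments approach zero).
#'
#' @param base Base-case `ntg_params`.
#' @param strat Positive-arm `ntg_strategy`.
#' @param spec An `ntg_psa_spec`.
#' @param seed Optional integer; when given, the RNG state is set for the
#'   draws and restored afterwards, making the result reproducible.
#' @return Object of class `ntg_psa`: per-draw results (`$results`), the
#'   draw matrix (`$draws`), per-arm means, `icur_of_means`, its WTP
#'   classification, and the count of draws violating the utility ordering
#'   (which is deliberately not enforced per draw).
#' @examples
#' psa <- run_psa(ntg_parameters(), strategy("positive", 0.5),
#'                psa_spec(2000), seed = 1)
#' psa$icur_of_means
#' @export
run_psa <- function(base, strat = strategy("positive", 0.5),
                    spec = psa_spec(), seed = NULL) {
  base <- validate_parameters(base)
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      stats::runif(1)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  draws <- psa_draw_matrix(base, spec, spec$n_samples)
  res <- psa_evaluate(draws, base, strat)
  mean_dc <- mean(res$cost_positive) - mean(res$cost_traditional)
  mean_dq <- mean(res$qaly_positive) - mean(res$qaly_traditional)
  viol <- sum(draws[, "u_mild"] < draws[, "u_moderate"] |
                draws[, "u_moderate"] < draws[, "u_severe"])
  im <- if (mean_dq == 0) NA_real_ else icur(mean_dc, mean_dq)
  structure(list(
    results = res, draws = draws, spec = spec, strategy = strat,
    mean_cost_positive = mean(res$cost_positive),
    mean_cost_traditional = mean(res$cost_traditional),
    mean_qaly_positive = mean(res$qaly_positive),
    mean_qaly_traditional = mean(res$qaly_traditional),
    mean_delta_cost = mean_dc, mean_delta_qaly = mean_dq,
    icur_of_means = im,
    wtp_class = if (is.numeric(im) && !is.na(im))
      wtp_classify(im, base$econ$gdp_per_capita) else "undefined",
    n_utility_order_violations = viol,
    gdp_per_capita = base$econ$gdp_per_capita
  ), class = "ntg_psa")
}

#' @export
print.ntg_psa <- function(x, ...) {
  cat(sprintf("NTG probabilistic sensitivity analysis: %d draws, SD = %.0f%% of mean\n",
              x$spec$n_samples, 100 * x$spec$sd_fraction))
  cat(sprintf("  positive arm: surgery rate %.0f%%, surgery cost x%g\n",
              100 * x$strategy$surgery_rate, x$strategy$surgery_cost_multiplier))
  cat(sprintf("  mean cost/person:  positive $%.2f, traditional $%.2f\n",
              x$mean_cost_positive, x$mean_cost_traditional))
  cat(sprintf("  mean QALYs/person: positive %.2f, traditional %.2f\n",
              x$mean_qaly_positive, x$mean_qaly_traditional))
  if (is.na(x$icur_of_means)) cat("  ICUR of means: undefined\n")
  else cat(sprintf("  ICUR of means: $%.2f per QALY (%s)\n",
                   x$icur_of_means, x$wtp_class))
  if (x$n_utility_order_violations > 0)
    cat(sprintf("  note: %d draws violated the utility ordering (not enforced)\n",
                x$n_utility_order_violations))
  invisible(x)
}

#' Cost-effectiveness plane for a PSA result
#'
#' Scatter of per-draw incremental QALYs against incremental cost, with
#' the 1x and 3x GDP willingness-to-pay rays.
#'
#' @param x An `ntg_psa`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ntg_psa <- function(x, ...) {
  dq <- x$results$qaly_positive - x$results$qaly_traditional
  dc <- x$results$cost_positive - x$results$cost_traditional
  graphics::plot(dq, dc, pch = ".", col = "#00000040",
                 xlab = "incremental QALYs", ylab = "incremental cost (USD)",
                 main = "Cost-effectiveness plane", ...)
  graphics::abline(0, x$gdp_per_capita, col = "#2c7fb8", lwd = 2)
  graphics::abline(0, 3 * x$gdp_per_capita, col = "#de2d26", lwd = 2, lty = 2)
  graphics::abline(h = 0, v = 0, col = "grey60")
  graphics::points(x$mean_delta_qaly, x$mean_delta_cost, pch = 19, col = "red")
  graphics::legend("topleft", c("1x GDP", "3x GDP", "mean"), bty = "n",
                   col = c("#2c7fb8", "#de2d26", "red"),
                   lty = c(1, 2, NA), pch = c(NA, NA, 19))
  invisible(x)
}
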