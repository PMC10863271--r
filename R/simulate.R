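#' Microsimulation of individual patient trajectories
#'
#' Samples each patient's annual state path from the same per-cycle
#' transition matrices as the deterministic cohort engine, so the empirical
#' state frequencies converge to the [run_cohort()] trace (this is the
#' cross-validation oracle for the cohort engine). Patients start mild;
#' in the positive arm, surgery is assigned at entry with probability
#' `strat$surgery_rate` and fails with probability
#' `costs$surgical_failure_rate`.
#'
#' @param params An `ntg_params`.
#' @param strat An `ntg_strategy` (default all-medication positive arm).
#' @param n Number of patients (>= 1).
#' @param seed Optional integer; RNG state is set and restored as in
#'   [stats::simulate()].
#' @param age_jitter Non-negative integer; when positive, entry ages are
#'   drawn uniformly from `start_age + (-age_jitter:age_jitter)`. The
#'   cohort of the base analysis is homogeneous at entry (all aged 64), so
#'   the default is 0; the knob exists for robustness checks only.
#' @return Object of class `ntg_patients`: integer state matrix `states`
#'   (`n` rows, horizon + 1 columns, coded 1 = mild ... 4 = dead), entry
#'   ages, surgery flags, and the generating arm.
#' @examples
#' pats <- simulate_patients(ntg_parameters(), n = 500, seed = 42)
#' table(NTG_STATES[pats$states[, 11]])
#' @export
simulate_patients <- function(params, strat = strategy("positive"), n,
                              seed = NULL, age_jitter = 0) {
  params <- validate_parameters(params)
  stopifnot(n >= 1, age_jitter >= 0)
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      stats::runif(1)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  h <- params$econ$horizon
  arm <- strat$arm
  tr <- params$transitions
  p12 <- if (arm == "positive") tr$p_mild_to_moderate_positive else
    tr$p_mild_to_moderate_traditional
  p23 <- if (arm == "positive") tr$p_moderate_to_severe_positive else
    tr$p_moderate_to_severe_traditional

  ages <- rep(params$econ$start_age, n)
  if (age_jitter > 0)
    ages <- ages + sample(seq(-age_jitter, age_jitter), n, replace = TRUE)

  q_for <- function(age_end) {
    b <- params$mortality$bands
    vapply(age_end, function(a) {
      i <- which(a >= b$age_from & a <= b$age_to)
      if (length(i) == 0) {
        if (a < min(b$age_from)) i <- which.min(b$age_from)
        else stop("attained age ", a, " is outside the mortality-table coverage",
                  call. = FALSE)
      }
      adjust_mortality(b$p_death[i[1]], params$mortality$glaucoma_odds_ratio)
    }, 0)
  }

  states <- matrix(1L, n, h + 1)
  for (k in 0:(h - 1)) {
    s <- states[, k + 1]
    q <- q_for(ages + k + 1)
    u <- stats::runif(n)
    nxt <- s
    ## additive competing events: die with prob q, progress with prob p,
    ## stay otherwise; dead (4) is absorbing
    m1 <- s == 1L
    nxt[m1 & u < q] <- 4L
    nxt[m1 & u >= q & u < q + p12] <- 2L
    m2 <- s == 2L
    nxt[m2 & u < q] <- 4L
    nxt[m2 & u >= q & u < q + p23] <- 3L
    m3 <- s == 3L
    nxt[m3 & u < q] <- 4L
    states[, k + 2] <- nxt
  }

  surgery_assigned <- if (arm == "positive" && strat$surgery_rate > 0)
    stats::runif(n) < strat$surgery_rate else rep(FALSE, n)
  surgery_failed <- surgery_assigned &
    stats::runif(n) < params$costs$surgical_failure_rate

  structure(list(
    arm = arm, n = n, states = states, age_at_entry = ages,
    surgery_assigned = surgery_assigned, surgery_failed = surgery_failed
  ), class = "ntg_patients")
}

#' @export
print.ntg_patients <- function(x, ...) {
  h <- ncol(x$states) - 1
  cat(sprintf("NTG microsimulation: %d patients, %s arm, %d cycles\n",
              x$n, x$arm, h))
  cat("  final states: ",
      paste(sprintf("%s %.1f%%", NTG_STATES,
                    100 * tabulate(x$states[, h + 1], 4) / x$n),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Empirical state-occupancy trace of a microsimulation
#'
#' Per-cycle fraction of patients in each state, directly comparable to
#' the `occupancy` matrix of an [run_cohort()] trace.
#'
#' @param patients An `ntg_patients` object.
#' @return `(horizon + 1) x 4` matrix of state fractions.
#' @export
empirical_trace <- function(patients) {
  stopifnot(inherits(patients, "ntg_patients"))
  t(apply(patients$states, 2, function(s) tabulate(s, 4) / patients$n))
}

#' Long-format patient-cycle table
#'
#' One row per patient-cycle, suitable for CSV export and external
#' inspection.
#'
#' @param x An `ntg_patients` object.
#' @param ... Unused.
#' @export
as.data.frame.ntg_patients <- function(x, ...) {
  h <- ncol(x$states) - 1
  data.frame(
    id = rep(seq_len(x$n), each = h + 1),
    cycle = rep(0:h, times = x$n),
    state = NTG_STATES[t(x$states)],
    age_at_entry = rep(x$age_at_entry, each = h + 1),
    surgery_assigned = rep(x$surgery_assigned, each = h + 1),
    surgery_failed = rep(x$surgery_failed, each = h + 1),
    row.names = NULL
  )
}

#' Simulate patients from a fitted comparison
#'
#' Draws individual patient trajectories under the fitted model's
#' parameters, for either arm.
#'
#' @param object An `ntg_cua` from [compare_strategies()].
#' @param nsim Number of patients.
#' @param seed Optional integer seed.
#' @param arm Which arm to simulate (default the positive arm).
#' @param ... Passed to [simulate_patients()].
#' @return An `ntg_patients` object.
#' @export
simulate.ntg_cua <- function(object, nsim = 1000, seed = NULL,
                             arm = c("positive", "traditional"), ...) {
  arm <- match.arg(arm)
  st <- if (arm == "positive") object$strategy_positive else strategy("traditional")
  simulate_patients(object$params, st, n = nsim, seed = seed, ...)
}
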