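#' Health states of the NTG disease model
#'
#' Ordered disease severity states used throughout the package. `"dead"` is
#' absorbing; within one annual cycle the model allows progression only to
#' the next severity stage (no skipping, no regression).
#'
#' @format Character vector of length 4.
#' @export
NTG_STATES <- c("mild", "moderate", "severe", "dead")

ntg_default_parameters <- function() {
  list(
    transitions = list(
      p_mild_to_moderate_positive    = 0.044,
      p_moderate_to_severe_positive  = 0.018,
      p_mild_to_moderate_traditional = 0.149,
      p_moderate_to_severe_traditional = 0.056
    ),
    utilities = list(
      u_mild = 0.80, u_moderate = 0.75, u_severe = 0.71, u_dead = 0
    ),
    mortality = list(
      bands = data.frame(
        age_from = c(65, 70),
        age_to   = c(69, 74),
        p_death  = c(0.00364, 0.00518)
      ),
      glaucoma_odds_ratio = 1.8
    ),
    costs = list(
      annual_dual_therapy    = 307.24,
      annual_triple_therapy  = 470.45,
      trabeculectomy         = 530.97,
      followup_no_progression = 79.55,
      followup_progression   = 119.32,
      first_year_moderate_B  = 381.84,
      first_year_severe_B    = 381.84,
      consecutive_year_moderate_B = 254.56,
      consecutive_year_severe_B   = 254.56,
      dual_to_triple_ratio   = 3,
      dose_multiplier_after_progression = 1.5,
      surgical_failure_rate  = 0.20
    ),
    econ = list(
      discount_rate = 0.035,
      horizon       = 10L,
      start_age     = 64,
      cohort_size   = 100000L,
      gdp_per_capita = 12692.90,
      half_cycle_correction = TRUE
    )
  )
}

#' Construct a validated model parameter set
#'
#' Builds the complete input set of the Markov model: annual transition
#' probabilities for both strategies, state utilities, an age-banded
#' mortality table with a glaucoma mortality odds ratio, all unit costs, and
#' the economic settings (discount rate, horizon, start age, willingness-to-
#' pay GDP per capita). Defaults are the base-case values of the underlying
#' Chinese NTG costing study; any component can be overridden by supplying a
#' named list with just the fields to change.
#'
#' @param transitions,utilities,mortality,costs,econ Named lists of
#'   overrides merged over the defaults. `mortality$bands` must be a data
#'   frame with columns `age_from`, `age_to`, `p_death`.
#' @return Object of class `ntg_params`: a list with components
#'   `transitions`, `utilities`, `mortality`, `costs`, `econ`.
#' @examples
#' p <- ntg_parameters()
#' p$transitions$p_mild_to_moderate_positive
#' p2 <- ntg_parameters(econ = list(discount_rate = 0))
#' @seealso [read_parameters()], [parameter_preset()], [compare_strategies()]
#' @export
ntg_parameters <- function(transitions = list(), utilities = list(),
                           mortality = list(), costs = list(), econ = list()) {
  p <- ntg_default_parameters()
  merge_over <- function(base, over, where) {
    if (length(over) == 0) return(base)
    nm <- names(over)
    if (is.null(nm) || any(!nzchar(nm)))
      stop("overrides for '", where, "' must be a named list", call. = FALSE)
    bad <- setdiff(nm, names(base))
    if (length(bad))
      stop("unknown parameter '", where, ".", bad[1], "'", call. = FALSE)
    base[nm] <- over
    base
  }
  p$transitions <- merge_over(p$transitions, transitions, "transitions")
  p$utilities   <- merge_over(p$utilities, utilities, "utilities")
  p$mortality   <- merge_over(p$mortality, mortality, "mortality")
  p$costs       <- merge_over(p$costs, costs, "costs")
  p$econ        <- merge_over(p$econ, econ, "econ")
  class(p) <- "ntg_params"
  validate_parameters(p)
}

#' Validate a model parameter set
#'
#' Checks every structural invariant of the parameter set: probabilities and
#' utilities in range and correctly ordered (treated-arm progression no
#' faster than traditional, utilities non-increasing with severity), costs
#' non-negative, mortality bands covering positive probabilities, and
#' economic settings admissible. Called by [ntg_parameters()] and
#' [read_parameters()]; errors name the offending field and bound.
#'
#' @param p An `ntg_params` object (or a bare list with the same shape).
#' @return `p`, invisibly classed as `ntg_params`, if valid.
#' @export
validate_parameters <- function(p) {
  need <- c("transitions", "utilities", "mortality", "costs", "econ")
  miss <- setdiff(need, names(p))
  if (length(miss))
    stop("parameter set is missing component '", miss[1], "'", call. = FALSE)

  chk_prob <- function(x, field, upper_open = FALSE) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x))
      stop("'", field, "' must be a single number", call. = FALSE)
    if (x < 0 || x > 1 || (upper_open && x == 1))
      stop("'", field, "' must lie in [0, 1", if (upper_open) ")" else "]",
           "; got ", x, call. = FALSE)
  }
  tr <- p$transitions
  for (f in names(ntg_default_parameters()$transitions)) {
    if (is.null(tr[[f]])) stop("missing transition probability '", f, "'", call. = FALSE)
    chk_prob(tr[[f]], paste0("transitions.", f))
  }
  if (tr$p_mild_to_moderate_positive > tr$p_mild_to_moderate_traditional)
    stop("'transitions.p_mild_to_moderate_positive' exceeds the traditional-arm ",
         "probability: treatment must not accelerate progression", call. = FALSE)
  if (tr$p_moderate_to_severe_positive > tr$p_moderate_to_severe_traditional)
    stop("'transitions.p_moderate_to_severe_positive' exceeds the traditional-arm ",
         "probability: treatment must not accelerate progression", call. = FALSE)

  u <- p$utilities
  for (f in c("u_mild", "u_moderate", "u_severe", "u_dead"))
    chk_prob(u[[f]], paste0("utilities.", f))
  if (!(u$u_dead <= u$u_severe && u$u_severe <= u$u_moderate &&
        u$u_moderate <= u$u_mild))
    stop("utilities must satisfy u_dead <= u_severe <= u_moderate <= u_mild",
         call. = FALSE)

  m <- p$mortality
  b <- m$bands
  if (!is.data.frame(b) || !all(c("age_from", "age_to", "p_death") %in% names(b)))
    stop("'mortality.bands' must be a data frame with columns ",
         "age_from, age_to, p_death", call. = FALSE)
  if (any(b$p_death <= 0 | b$p_death >= 1))
    stop("'mortality.bands.p_death' entries must lie in (0, 1)", call. = FALSE)
  if (any(b$age_from > b$age_to))
    stop("'mortality.bands' has age_from > age_to", call. = FALSE)
  if (!is.numeric(m$glaucoma_odds_ratio) || m$glaucoma_odds_ratio <= 0)
    stop("'mortality.glaucoma_odds_ratio' must be > 0", call. = FALSE)

  cc <- p$costs
  money <- setdiff(names(ntg_default_parameters()$costs),
                   c("dual_to_triple_ratio", "dose_multiplier_after_progression",
                     "surgical_failure_rate"))
  for (f in money) {
    if (is.null(cc[[f]])) stop("missing cost input '", f, "'", call. = FALSE)
    if (!is.numeric(cc[[f]]) || cc[[f]] < 0)
      stop("'costs.", f, "' must be >= 0", call. = FALSE)
  }
  if (cc$dual_to_triple_ratio <= 0)
    stop("'costs.dual_to_triple_ratio' must be > 0", call. = FALSE)
  if (cc$dose_multiplier_after_progression < 1)
    stop("'costs.dose_multiplier_after_progression' must be >= 1", call. = FALSE)
  chk_prob(cc$surgical_failure_rate, "costs.surgical_failure_rate")

  e <- p$econ
  if (e$discount_rate < 0) stop("'econ.discount_rate' must be >= 0", call. = FALSE)
  if (e$horizon < 1) stop("'econ.horizon' must be >= 1", call. = FALSE)
  if (e$cohort_size < 1) stop("'econ.cohort_size' must be >= 1", call. = FALSE)
  if (e$gdp_per_capita <= 0) stop("'econ.gdp_per_capita' must be > 0", call. = FALSE)
  if (!is.logical(e$half_cycle_correction))
    stop("'econ.half_cycle_correction' must be TRUE or FALSE", call. = FALSE)

  class(p) <- "ntg_params"
  invisible(p)
}

#' @export
print.ntg_params <- function(x, ...) {
  cat("NTG Markov model parameters\n")
  tr <- x$transitions
  cat(sprintf("  progression /y  positive: %.3f (mild>mod), %.3f (mod>sev)\n",
              tr$p_mild_to_moderate_positive, tr$p_moderate_to_severe_positive))
  cat(sprintf("                  traditional: %.3f (mild>mod), %.3f (mod>sev)\n",
              tr$p_mild_to_moderate_traditional, tr$p_moderate_to_severe_traditional))
  cat(sprintf("  utilities: %.2f / %.2f / %.2f (mild/moderate/severe)\n",
              x$utilities$u_mild, x$utilities$u_moderate, x$utilities$u_severe))
  cat(sprintf("  mortality OR %.1f over %d age bands\n",
              x$mortality$glaucoma_odds_ratio, nrow(x$mortality$bands)))
  cat(sprintf("  horizon %d y from age %g, discount %.1f%%, WTP GDP $%.2f\n",
              x$econ$horizon, x$econ$start_age, 100 * x$econ$discount_rate,
              x$econ$gdp_per_capita))
  invisible(x)
}

## flatten/unflatten between nested lists and dotted keys ("costs.trabeculectomy")
flatten_params <- function(p) {
  out <- list()
  for (comp in c("transitions", "utilities", "costs", "econ")) {
    for (f in names(p[[comp]])) out[[paste(comp, f, sep = ".")]] <- p[[comp]][[f]]
  }
  out[["mortality.glaucoma_odds_ratio"]] <- p$mortality$glaucoma_odds_ratio
  b <- p$mortality$bands
  out[["mortality.bands.age_from"]] <- b$age_from
  out[["mortality.bands.age_to"]] <- b$age_to
  out[["mortality.bands.p_death"]] <- b$p_death
  out
}

unflatten_params <- function(flat) {
  over <- list(transitions = list(), utilities = list(), mortality = list(),
               costs = list(), econ = list())
  band <- list()
  for (key in names(flat)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) == 3 && parts[1] == "mortality" && parts[2] == "bands") {
      band[[parts[3]]] <- unlist(flat[[key]])
    } else if (length(parts) == 2 && parts[1] %in% names(over)) {
      val <- flat[[key]]
      if (parts[2] == "half_cycle_correction") val <- as.logical(val)
      over[[parts[1]]][[parts[2]]] <- val
    } else {
      stop("unknown configuration key '", key, "'", call. = FALSE)
    }
  }
  if (length(band)) {
    need <- setdiff(c("age_from", "age_to", "p_death"), names(band))
    if (length(need))
      stop("mortality band table is missing column '", need[1], "'", call. = FALSE)
    over$mortality$bands <- data.frame(age_from = band$age_from,
                                       age_to = band$age_to,
                                       p_death = band$p_death)
  }
  over
}

#' Read model parameters from a YAML or JSON configuration file
#'
#' The configuration uses flat dotted keys mirroring the parameter fields
#' (e.g. `costs.trabeculectomy: 530.97`); nested maps with the same path
#' structure are accepted too. Keys omitted from the file keep their default
#' (base-case) values, so an empty file yields [ntg_parameters()]. The
#' dialect is chosen from the file extension (`.json` for JSON, anything
#' else parsed as YAML, of which JSON is a subset).
#'
#' @param path Path to the configuration file.
#' @return A validated `ntg_params` object.
#' @examples
#' cfg <- tempfile(fileext = ".yaml")
#' writeLines("transitions.p_mild_to_moderate_positive: 0.085", cfg)
#' read_parameters(cfg)$transitions$p_mild_to_moderate_positive
#' @export
read_parameters <- function(path) {
  if (!file.exists(path))
    stop("configuration file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  flat <- flatten_config_tree(raw)
  over <- unflatten_params(flat)
  do.call(ntg_parameters, over)
}

## accepts either flat dotted keys or nested maps; returns flat dotted keys
flatten_config_tree <- function(x, prefix = "") {
  out <- list()
  for (nm in names(x)) {
    key <- if (nzchar(prefix)) paste(prefix, nm, sep = ".") else nm
    val <- x[[nm]]
    if (is.list(val) && !is.data.frame(val) && !is.null(names(val))) {
      out <- c(out, flatten_config_tree(val, key))
    } else {
      out[[key]] <- val
    }
  }
  out
}

#' Write model parameters to a YAML or JSON configuration file
#'
#' Serialises the full parameter set as flat dotted keys, so that
#' `read_parameters(write_parameters(p, f))` round-trips to an equal set.
#'
#' @param p An `ntg_params` object.
#' @param path Destination file; `.json` writes JSON, otherwise YAML.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(p, path) {
  p <- validate_parameters(p)
  flat <- flatten_params(p)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(flat, path)
  }
  invisible(path)
}

#' Named parameter presets
#'
#' Fully specified parameter sets for standard model configurations:
#' \describe{
#'   \item{`base_case`}{The base case: tertiary-hospital annual
#'     progression probabilities (0.044 / 0.018 under positive treatment)
#'     and all default costs and utilities.}
#'   \item{`alternative_rates`}{Positive-arm progression set to the
#'     visual-field-slope-derived annual rates 0.085 (mild to moderate) and
#'     0.035 (moderate to severe).}
#'   \item{`stress_zero_progression`}{All four progression probabilities 0;
#'     the cohort only dies. Useful as a degenerate stress case.}
#'   \item{`stress_high_mortality`}{Ten-fold background mortality, for
#'     exercising the mortality machinery.}
#' }
#'
#' @param name Preset name.
#' @return A validated `ntg_params` object.
#' @export
parameter_preset <- function(name = c("base_case", "alternative_rates",
                                      "stress_zero_progression",
                                      "stress_high_mortality")) {
  name <- match.arg(name)
  switch(name,
    base_case = ntg_parameters(),
    alternative_rates = ntg_parameters(transitions = list(
      p_mild_to_moderate_positive = 0.085,
      p_moderate_to_severe_positive = 0.035
    )),
    stress_zero_progression = ntg_parameters(transitions = list(
      p_mild_to_moderate_positive = 0,
      p_moderate_to_severe_positive = 0,
      p_mild_to_moderate_traditional = 0,
      p_moderate_to_severe_traditional = 0
    )),
    stress_high_mortality = {
      p <- ntg_parameters()
      p$mortality$bands$p_death <- 10 * p$mortality$bands$p_death
      validate_parameters(p)
      p
    }
  )
}
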