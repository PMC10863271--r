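#' Convert a multi-year probability to an instantaneous annual rate
#'
#' Under the standard constant-hazard assumption, a probability `p` of the
#' event occurring within `t` years corresponds to the continuous-time rate
#' `-log(1 - p) / t` (events per person-year). This is how a 5-year
#' progression probability (e.g. the 0.20 observed over 5 years under
#' IOP-lowering treatment) is reduced to an annual hazard before being
#' re-expressed as a 1-year transition probability with [rate_to_prob()].
#'
#' @param p Probability of the event over `t` years; must lie in `[0, 1)`.
#' @param t Exposure time in years; must be positive.
#' @return Rate in events per person-year.
#' @examples
#' prob_to_rate(0.20, 5)            # 0.0446287
#' rate_to_prob(prob_to_rate(0.20, 5), 1)   # ~0.0436, the "4% per year"
#' @export
prob_to_rate <- function(p, t = 1) {
  stopifnot(is.numeric(p), is.numeric(t))
  if (any(t <= 0)) stop("'t' must be > 0", call. = FALSE)
  if (any(p < 0 | p > 1)) stop("'p' must lie in [0, 1)", call. = FALSE)
  if (any(p == 1))
    stop("'p' = 1 corresponds to an infinite rate", call. = FALSE)
  -log1p(-p) / t
}

#' Convert an instantaneous annual rate to a probability over t years
#'
#' Inverse of [prob_to_rate()]: the probability of at least one event in
#' `t` years under a constant hazard `r` is `1 - exp(-r * t)`.
#'
#' @param r Rate in events per person-year; must be non-negative.
#' @param t Exposure time in years; must be positive.
#' @return Probability in `[0, 1)`.
#' @export
rate_to_prob <- function(r, t = 1) {
  stopifnot(is.numeric(r), is.numeric(t))
  if (any(t <= 0)) stop("'t' must be > 0", call. = FALSE)
  if (any(r < 0)) stop("'r' must be >= 0", call. = FALSE)
  -expm1(-r * t)
}
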