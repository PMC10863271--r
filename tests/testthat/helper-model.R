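## Shared fixtures for the model tests. Everything is built in code; the
## default parameter set is cheap to construct, so tests rebuild it freely.

base_params <- function() ntg_parameters()

## parameters with the positive arm forced equal to the traditional arm
identical_arm_params <- function() {
  ntg_parameters(transitions = list(
    p_mild_to_moderate_positive = 0.149,
    p_moderate_to_severe_positive = 0.056
  ))
}

## near-degenerate mortality for stress cases (validation requires > 0)
no_death_params <- function(...) {
  p <- ntg_parameters(...)
  p$mortality$bands$p_death <- c(1e-12, 1e-12)
  validate_parameters(p)
  p
}

## binomial tolerance: 3 standard errors, with a floor for fractions at 0/1
binom_tol <- function(p, n, floor = 1e-9) pmax(3 * sqrt(p * (1 - p) / n), floor)
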