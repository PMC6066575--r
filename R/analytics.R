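#' Per-round payoff variance of the selfish strategy
#'
#' Among selfish foragers, a fraction `p` obtain `R` units on a given round
#' and the rest obtain nothing, giving a per-round payoff variance of
#' `(1 - p) * p * R^2`. Fair agents that pool and divide each round have
#' zero within-pool variance, while both strategies share the expected
#' payoff `p * R` - the variance contrast is the model's engine of
#' selection.
#'
#' @param R Mean resource units per success.
#' @param p Success probability.
#' @return The variance in resource units squared.
#' @examples
#' payoff_variance(40, 0.0875)  # 127.75
#' payoff_variance(10, 0.35)    # 22.75
#' @export
payoff_variance <- function(R, p) {
  stopifnot(all(R >= 0), all(p >= 0 & p <= 1))
  (1 - p) * p * R^2
}

#' Expected per-step foraging payoff
#'
#' @inheritParams payoff_variance
#' @return `p * R` resource units per step.
#' @examples
#' expected_payoff(40, 0.0875)  # 3.5
#' @export
expected_payoff <- function(R, p) {
  stopifnot(all(R >= 0), all(p >= 0 & p <= 1))
  p * R
}

#' Expected cumulative payoff over a reproductive delay
#'
#' The resources an agent expects to accumulate over `d` foraging rounds,
#' `d * p * R`.
#'
#' @param d Delay in steps.
#' @inheritParams payoff_variance
#' @return Expected resource units.
#' @examples
#' cumulative_expected_payoff(10, 0.125, 40)  # 50
#' @export
cumulative_expected_payoff <- function(d, p, R) {
  stopifnot(all(d >= 0))
  d * expected_payoff(R, p)
}

#' Probability a selfish agent reaches the threshold within the delay
#'
#' The probability of at least `k` foraging successes in `d` rounds,
#' `P(X >= k)` for `X ~ Binomial(d, p)`, computed with the stable binomial
#' tail. A selfish agent needs about `k = ceiling(P * T / R)` successes to
#' replace the resources invested in one offspring, so a small tail
#' probability means selfish reproduction is bottlenecked by the delay
#' while fair agents accumulate the pooled mean steadily.
#'
#' @param d Number of rounds (the reproductive delay).
#' @param p Per-round success probability.
#' @param k Required number of successes; defaults to
#'   [required_successes()] for the standard thresholds.
#' @return A probability.
#' @examples
#' prob_reach_threshold(10, 0.125, 2)  # about 0.361
#' @export
prob_reach_threshold <- function(d, p, k = required_successes()) {
  stopifnot(all(d >= 0), all(d == floor(d)), all(k >= 0), all(k == floor(k)),
            all(p >= 0 & p <= 1))
  stats::pbinom(k - 1, size = d, prob = p, lower.tail = FALSE)
}

#' Foraging successes needed to replace one reproductive investment
#'
#' A parent at threshold `T` transfers about `P * T` units to an offspring,
#' so a selfish forager needs `ceiling(P * T / R)` successes of size `R` to
#' restock. The defaults (P = 0.5, T = 100, R = 40) give k = 2.
#'
#' @param P Parental investment fraction.
#' @param T Reproductive threshold in resource units.
#' @param R Resource units per success.
#' @return An integer count of required successes.
#' @export
required_successes <- function(P = 0.5, T = 100, R = 40) {
  stopifnot(all(R > 0))
  as.integer(ceiling(P * T / R))
}

#' Delay at which selection for fairness peaks
#'
#' Selection for fairness is most intense when the expected accumulation
#' over the delay just replaces the resources invested in one offspring:
#' `d * p * R = P * T`, i.e. `d = P * T / (p * R)`. Returned as a real
#' number; round to the nearest integer delay for comparison with sweeps.
#'
#' @param P Parental investment fraction.
#' @param T Reproductive threshold.
#' @param p Foraging success probability.
#' @param R Resource units per success.
#' @return The predicted peak delay in steps.
#' @examples
#' predicted_peak_delay(0.5, 100, 0.0875, 40)  # about 14.3
#' @export
predicted_peak_delay <- function(P, T, p, R) {
  if (any(p * R <= 0))
    stop("expected payoff p * R must be positive", call. = FALSE)
  P * T / (p * R)
}

#' Play-gene birth frequency over a measurement window
#'
#' The fraction of agents born within the window that carried the play gene
#' at birth (post-mutation state). With no births in the window the
#' frequency is undefined and `NA` is returned (never silently 0), with the
#' birth count attached as attribute `n_births`.
#'
#' @param birth_log Data frame with columns `step` and `gene` (0/1 or
#'   logical), one row per birth.
#' @param window Inclusive `[start, end]` step range.
#' @return The frequency as a fraction, with attribute `n_births`.
#' @export
gene_birth_frequency <- function(birth_log, window) {
  stopifnot(length(window) == 2L, window[1] <= window[2])
  sel <- birth_log$step >= window[1] & birth_log$step <= window[2]
  n <- sum(sel)
  out <- if (n == 0L) NA_real_ else sum(birth_log$gene[sel] > 0) / n
  attr(out, "n_births") <- n
  out
}

#' Realized play-mortality percentage
#'
#' `100 * play_deaths / playing_juveniles`, where the denominator is the
#' number of juveniles that entered at least one play bout; 0 when no
#' juvenile ever played.
#'
#' @param play_deaths Number of juveniles that died during play.
#' @param playing_juveniles Number of juveniles that played at least once.
#' @return A percentage.
#' @export
play_mortality_percent <- function(play_deaths, playing_juveniles) {
  if (play_deaths < 0 || playing_juveniles < 0)
    stop("counts must be non-negative", call. = FALSE)
  if (playing_juveniles < play_deaths)
    stop("play_deaths cannot exceed playing_juveniles", call. = FALSE)
  if (playing_juveniles == 0) return(0)
  100 * play_deaths / playing_juveniles
}
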