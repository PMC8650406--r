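#' Convert an event proportion to a constant daily rate
#'
#' Under a constant-hazard (exponential) model, a proportion `P` of a cohort
#' experiencing an event over a follow-up window of `t` days implies the
#' daily rate `r = -log(1 - P) / t`.
#'
#' @param P Event proportion observed over the window, in `[0, 1)`.
#' @param t Length of the follow-up window in days (> 0).
#' @return Event rate per day (non-negative scalar).
#' @seealso [rate_to_prob()], [rescale_prob()]
#' @export
#' @examples
#' prob_to_rate(0.5, 182.5)   # 50% relapse over six months
prob_to_rate <- function(P, t) {
  stopifnot(is.numeric(P), is.numeric(t))
  if (any(P < 0 | P >= 1)) stop("P must lie in [0, 1): got ", P[P < 0 | P >= 1][1])
  if (any(t <= 0)) stop("t must be positive")
  -log(1 - P) / t
}

#' Convert a constant daily rate to a probability over a window
#'
#' Inverse of [prob_to_rate()]: `p = 1 - exp(-r t)`.
#'
#' @param r Event rate per day (>= 0).
#' @param t Window length in days (> 0).
#' @return Event probability over the window, in `[0, 1)`.
#' @export
rate_to_prob <- function(r, t) {
  stopifnot(is.numeric(r), is.numeric(t))
  if (any(r < 0)) stop("r must be non-negative")
  if (any(t <= 0)) stop("t must be positive")
  1 - exp(-r * t)
}

#' Rescale an event probability to a different time window
#'
#' Composes [prob_to_rate()] and [rate_to_prob()] under the constant-hazard
#' assumption. This is how the model's 30-day cycle probabilities are derived
#' from source-trial proportions reported over arbitrary follow-up windows.
#' The conversion ignores competing risks, matching standard decision-model
#' practice.
#'
#' @param P Event proportion over the source window.
#' @param t_source Source window in days.
#' @param t_target Target window in days (the model cycle is 30 days).
#' @return Probability over `t_target` days.
#' @export
#' @examples
#' rescale_prob(0.50, 182.5, 30)  # relapse on standard treatment after ECT
#' rescale_prob(0.31, 365, 30)    # relapse while receiving maintenance ECT
#' rescale_prob(0.267, 17.7 * 7, 30)  # relapse on esketamine maintenance
rescale_prob <- function(P, t_source, t_target) {
  rate_to_prob(prob_to_rate(P, t_source), t_target)
}

#' Rescale a mortality proportion with a relative-risk multiplier
#'
#' Applies a hazard-ratio style multiplier on the rate scale before
#' converting back to a probability: used for the excess mortality of
#' treatment-resistant depression relative to depression (multiplier 1.35
#' applied to 11.6% all-cause mortality over 4.5 years).
#'
#' @param P Source event proportion.
#' @param t Source window in days.
#' @param rr Relative-risk multiplier on the rate scale (> 0).
#' @param t_target Target window in days.
#' @return Probability over `t_target` days.
#' @export
#' @examples
#' mortality_with_relative_risk(0.116, 4.5 * 365, 1.35, 30)
mortality_with_relative_risk <- function(P, t, rr, t_target) {
  if (any(rr <= 0)) stop("rr must be positive")
  rate_to_prob(rr * prob_to_rate(P, t), t_target)
}
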