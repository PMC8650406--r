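# run expr under a private RNG stream seeded by `seed`, restoring any
# global state afterwards
with_rng <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Source-trial evidence summaries behind the derivable transition inputs
#'
#' The event proportions and follow-up windows from which five of the model's
#' per-cycle transition probabilities are derived via the constant-hazard
#' conversion: relapse on standard treatment after successful ECT (50% over
#' six months), relapse on maintenance ECT (31% over one year), relapse on
#' esketamine maintenance (26.7% over 17.7 weeks), remission on standard
#' treatment (13.7% over 5.6 weeks), and depression mortality (11.6%
#' all-cause over 4.5 years, raised by a relative risk of 1.35 for
#' treatment resistance).
#'
#' @return Data frame with columns `param`, `P`, `window_days`, `rr`.
#' @export
evidence_summaries <- function() {
  data.frame(
    param = c("tpB2C_ect", "tpB2C_mect", "tpB2C_esk", "tpD2E", "tpDep2G"),
    P = c(0.50, 0.31, 0.267, 0.137, 0.116),
    window_days = c(182.5, 365, 17.7 * 7, 5.6 * 7, 4.5 * 365),
    rr = c(1, 1, 1, 1, 1.35),
    stringsAsFactors = FALSE)
}

#' Simulate a binary-outcome trial
#'
#' Draws i.i.d. Bernoulli outcomes with the statistical structure of the
#' source trials the model's transition probabilities come from: a single
#' event proportion observed over a fixed follow-up window.
#'
#' @param n Number of patients.
#' @param p_window True event probability over the window.
#' @param window_days Follow-up window, days.
#' @param seed Integer seed (private stream; the global RNG state is left
#'   untouched).
#' @param rr Relative-risk multiplier to apply on the rate scale when the
#'   per-cycle probability is estimated (1 for none).
#' @return A list of class `trd_trial` with the outcomes and design fields.
#' @export
simulate_trial <- function(n, p_window, window_days, seed, rr = 1) {
  stopifnot(n > 0, p_window >= 0, p_window <= 1, window_days > 0)
  outcomes <- with_rng(seed, stats::rbinom(n, 1L, p_window))
  structure(list(n = n, p_window = p_window, window_days = window_days,
                 rr = rr, seed = seed, outcomes = outcomes),
            class = "trd_trial")
}

#' Per-cycle probability estimated from a simulated trial
#'
#' Applies the model's own derivation chain to the observed proportion:
#' proportion -> daily rate (times any relative-risk multiplier) ->
#' probability over the target window.
#'
#' @param trial A `trd_trial`.
#' @param t_target Target window in days (model cycle, 30).
#' @return Estimated per-cycle probability.
#' @export
trial_cycle_prob <- function(trial, t_target = 30) {
  p_hat <- mean(trial$outcomes)
  if (p_hat >= 1) stop("all patients had the event; rate undefined")
  mortality_with_relative_risk(p_hat, trial$window_days, trial$rr, t_target)
}

#' Recover transition inputs from a set of synthetic trials
#'
#' Runs the derivation chain in reverse over one trial per derivable
#' parameter. With noiseless proportions (or n large) the estimates converge
#' on the per-cycle inputs of [trd_parameters()].
#'
#' @param trials Named list of `trd_trial` objects; names identify the
#'   transition parameter each trial informs (as in [evidence_summaries()]).
#' @param t_target Target window, days.
#' @return Named numeric vector of per-cycle probability estimates (empty
#'   for an empty list).
#' @export
recover_parameters <- function(trials, t_target = 30) {
  vapply(trials, trial_cycle_prob, numeric(1), t_target = t_target)
}

#' Individual-level microsimulation of the cohort model
#'
#' Simulates `n` individuals through the same expanded state space with
#' per-cycle categorical draws, accruing discounted cost and QALYs through
#' the same costing, utility and discounting code paths as [run_cohort()].
#' Serves as an independent Monte-Carlo oracle for the deterministic cohort
#' recursion: disagreement beyond Monte-Carlo error isolates a defect in the
#' recursion, not in the accounting.
#'
#' @param settings Run settings (half-cycle correction is not supported
#'   here).
#' @param params Parameter bundle.
#' @param n Number of simulated individuals.
#' @param seed Integer seed (private stream).
#' @param scenario Scenario modifications.
#' @param keep_paths Record every individual's state path (memory scales
#'   with `n * cycles`; intended for small `n`).
#' @return A list of class `trd_microsim`: `n`, `mean_cost`, `se_cost`,
#'   `mean_qaly`, `se_qaly`, and `paths` (state-label matrix, individuals by
#'   cycles+1) when `keep_paths = TRUE`.
#' @export
microsimulate <- function(settings, params = trd_parameters(), n = 10000,
                          seed = 1, scenario = scenario_mods(),
                          keep_paths = FALSE) {
  if (isTRUE(settings$half_cycle_correction))
    stop("the microsimulation oracle accrues whole cycles; ",
         "run it with half_cycle_correction = FALSE")
  if (!is.na(scenario$horizon_years))
    settings$horizon_years <- scenario$horizon_years
  if (!is.na(scenario$discount_rate))
    settings$discount_rate <- scenario$discount_rate
  arm <- settings$arm; variant <- settings$variant
  states <- expanded_states(arm, variant)
  ns <- length(states)
  n_cycles <- round(settings$horizon_years * settings$cycles_per_year)
  u_ann <- state_utilities_annual(states, arm, params, scenario)
  u_cycle <- if (isTRUE(params$utilities$use_rounded_cycle))
    ifelse(states %in% c("A", "C", "D"), 0.05,
           ifelse(states == "G", 0, 0.07))
  else u_ann / settings$cycles_per_year
  ages <- settings$start_age + (seq_len(n_cycles) - 1L) %/%
    settings$cycles_per_year
  uniq_ages <- unique(ages)
  cum_by_age <- cost_by_age <- list()
  for (age in uniq_ages) {
    mr <- band_mortality(age, params$transitions$remission_mortality)
    P <- transition_matrix(arm, variant, mr, params, scenario)
    cum_by_age[[as.character(age)]] <- t(apply(P, 1, cumsum))
    cost_by_age[[as.character(age)]] <- vapply(states, state_cycle_cost,
      numeric(1), arm = arm, variant = variant, age = age,
      perspective = settings$perspective, params = params,
      prod_mult = scenario$prod_mult, ect_sessions = scenario$ect_sessions,
      esk_indefinite = scenario$esk_indefinite)
  }
  state <- rep.int(1L, n)  # everyone starts depressed in A
  cost_i <- qaly_i <- numeric(n)
  paths <- if (keep_paths)
    matrix(NA_character_, n, n_cycles + 1) else NULL
  if (keep_paths) paths[, 1] <- states[state]
  with_rng(seed, {
    for (t in seq_len(n_cycles) - 1L) {
      key <- as.character(ages[t + 1])
      df <- discount_factor(t, settings)
      cost_i <- cost_i + df * cost_by_age[[key]][state]
      qaly_i <- qaly_i + df * u_cycle[state]
      cum <- cum_by_age[[key]]
      u <- stats::runif(n)
      nxt <- state
      for (s in unique(state)) {
        idx <- which(state == s)
        nxt[idx] <- findInterval(u[idx], cum[s, ],
                                 rightmost.closed = TRUE) + 1L
      }
      state <- pmin(nxt, ns)
      if (keep_paths) paths[, t + 2] <- states[state]
    }
  })
  structure(list(n = n,
                 mean_cost = mean(cost_i),
                 se_cost = stats::sd(cost_i) / sqrt(n),
                 mean_qaly = mean(qaly_i),
                 se_qaly = stats::sd(qaly_i) / sqrt(n),
                 paths = paths, settings = settings),
            class = "trd_microsim")
}

#' @export
print.trd_microsim <- function(x, ...) {
  cat(sprintf("<trd_microsim> n = %d individuals\n", x$n))
  cat(sprintf("  cost %s (SE %s) GBP; QALY %.3f (SE %.4f)\n",
              format(round(x$mean_cost), big.mark = ","),
              format(round(x$se_cost), big.mark = ","),
              x$mean_qaly, x$se_qaly))
  invisible(x)
}
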