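#' Expanded state space for a model configuration
#'
#' The published state labels A-G are expanded with tunnel states where
#' costs depend on time since entering remission: the esketamine arm splits
#' remission on esketamine into monthly tunnel states `B1`-`B6` followed by
#' `F` (remission on standard treatment), and the maintenance-ECT variant
#' splits remission into `B1` (month 1) and `B2p` (month 2 onwards).
#' `G` (death) is absorbing.
#'
#' @param arm `"ect"` or `"esk"`.
#' @param variant `"main"` or `"maintenance"`.
#' @return Character vector of state labels.
#' @export
expanded_states <- function(arm, variant = "main") {
  if (arm == "ect") {
    if (variant == "maintenance") c("A", "B1", "B2p", "C", "D", "E", "G")
    else c("A", "B", "C", "D", "E", "G")
  } else {
    c("A", paste0("B", 1:6), "F", "C", "D", "E", "G")
  }
}

#' Scenario modifications for a model run
#'
#' Collects every knob the deterministic sensitivity analyses turn. Defaults
#' reproduce the base case.
#'
#' @param tp Named list of transition-probability overrides. Recognised
#'   names: `tpA2B_ect`, `tpA2B_esk` (applied to states A *and* C),
#'   `tpC2B_ect`, `tpC2B_esk` (state C only, second treatment), `tpB2C_ect`,
#'   `tpB2C_mect`, `tpB2C_esk`, `tpD2E`, `tpE2D`, `tpDep2G`.
#' @param prod_mult Multiplier on the productivity-loss cost component.
#' @param ect_sessions ECT sessions per treatment cycle (base 8).
#' @param esk_indefinite Esketamine maintenance continues while in remission
#'   instead of switching to standard treatment after six months.
#' @param u_ect_treatment Annual utility override for the ECT arm's
#'   treatment states A and C (`NA` = base depression utility).
#' @param u_enhanced_remission Annual utility override for remission on
#'   standard treatment after a failed course (state E, both arms) and for
#'   remission on/after esketamine (tunnel states and F); the ECT arm's
#'   post-ECT remission keeps the base utility. `NA` = base.
#' @param horizon_years,discount_rate Overrides of the run settings (`NA` =
#'   keep).
#' @return A list of class `trd_scenario`.
#' @export
scenario_mods <- function(tp = list(), prod_mult = 1, ect_sessions = 8,
                          esk_indefinite = FALSE, u_ect_treatment = NA,
                          u_enhanced_remission = NA, horizon_years = NA,
                          discount_rate = NA) {
  known <- c("tpA2B_ect", "tpA2B_esk", "tpC2B_ect", "tpC2B_esk", "tpB2C_ect",
             "tpB2C_mect", "tpB2C_esk", "tpD2E", "tpE2D", "tpDep2G")
  bad <- setdiff(names(tp), known)
  if (length(bad)) stop("unknown transition override(s): ",
                        paste(bad, collapse = ", "))
  structure(list(tp = tp, prod_mult = prod_mult, ect_sessions = ect_sessions,
                 esk_indefinite = isTRUE(esk_indefinite),
                 u_ect_treatment = u_ect_treatment,
                 u_enhanced_remission = u_enhanced_remission,
                 horizon_years = horizon_years, discount_rate = discount_rate),
            class = "trd_scenario")
}

# effective transition inputs after scenario overrides
effective_transitions <- function(params, scenario) {
  tr <- params$transitions
  ov <- scenario$tp
  for (nm in c("tpA2B_ect", "tpA2B_esk", "tpB2C_ect", "tpB2C_mect",
               "tpB2C_esk", "tpD2E", "tpE2D", "tpDep2G"))
    if (!is.null(ov[[nm]])) tr[[nm]] <- ov[[nm]]
  # second-treatment (state C) remission defaults to the state-A value
  tr$tpC2B_ect <- if (!is.null(ov$tpC2B_ect)) ov$tpC2B_ect else tr$tpA2B_ect
  tr$tpC2B_esk <- if (!is.null(ov$tpC2B_esk)) ov$tpC2B_esk else tr$tpA2B_esk
  tr
}

#' Transition matrix for one age band
#'
#' Builds the full one-cycle transition matrix over the expanded state space.
#' Listed exit probabilities are applied simultaneously; the residual mass
#' defines the remaining ("stay" or "advance") transition. An error names
#' the state if listed exits already exceed 1.
#'
#' Arrows: A and C resolve within one cycle into first remission state,
#' death, or non-remission (-> D). Remission states relapse to C (re-treated
#' with the arm's therapy), die at the lifetable rate, or stay/advance
#' (esketamine tunnel months advance to F after month 6; maintenance-ECT
#' month 1 advances to the ongoing phase). D remits to E; E relapses to D
#' (standard treatment continues, no re-treatment).
#'
#' @param arm,variant Configuration (see [model_settings()]).
#' @param remission_mortality_cycle Per-cycle lifetable mortality for the
#'   current age band.
#' @param params Parameter bundle.
#' @param scenario Scenario modifications ([scenario_mods()]).
#' @return Row-stochastic matrix with dimnames from [expanded_states()].
#' @export
transition_matrix <- function(arm, variant, remission_mortality_cycle,
                              params = trd_parameters(),
                              scenario = scenario_mods()) {
  tr <- effective_transitions(params, scenario)
  mr <- remission_mortality_cycle
  states <- expanded_states(arm, variant)
  ns <- length(states)
  P <- matrix(0, ns, ns, dimnames = list(states, states))
  first_rem <- if (arm == "ect" && variant == "main") "B" else "B1"
  tpA2B <- if (arm == "ect") tr$tpA2B_ect else tr$tpA2B_esk
  tpC2B <- if (arm == "ect") tr$tpC2B_ect else tr$tpC2B_esk
  relapse <- if (arm == "esk") tr$tpB2C_esk
             else if (variant == "maintenance") tr$tpB2C_mect
             else tr$tpB2C_ect
  set_row <- function(state, exits) {
    tot <- sum(exits)
    if (tot > 1 + 1e-12)
      stop("transition probabilities out of state ", state,
           " sum to ", format(tot), " > 1")
    for (nm in names(exits)) P[state, nm] <<- P[state, nm] + exits[[nm]]
  }
  res <- function(state) 1 - sum(P[state, ])
  set_row("A", c(stats::setNames(tpA2B, first_rem), G = tr$tpDep2G))
  P["A", "D"] <- res("A")
  set_row("C", c(stats::setNames(tpC2B, first_rem), G = tr$tpDep2G))
  P["C", "D"] <- res("C")
  set_row("D", c(E = tr$tpD2E, G = tr$tpDep2G)); P["D", "D"] <- res("D")
  set_row("E", c(D = tr$tpE2D, G = mr)); P["E", "E"] <- res("E")
  if (arm == "ect" && variant == "main") {
    set_row("B", c(C = relapse, G = mr)); P["B", "B"] <- res("B")
  } else if (arm == "ect") {
    set_row("B1", c(C = relapse, G = mr)); P["B1", "B2p"] <- res("B1")
    set_row("B2p", c(C = relapse, G = mr)); P["B2p", "B2p"] <- res("B2p")
  } else {
    for (m in 1:6) {
      s <- paste0("B", m)
      nxt <- if (m < 6) paste0("B", m + 1)
             else if (scenario$esk_indefinite) "B6" else "F"
      set_row(s, c(C = relapse, G = mr)); P[s, nxt] <- P[s, nxt] + res(s)
    }
    # relapse from F behaves like relapse on standard treatment, but leads
    # to re-treatment (state C)
    set_row("F", c(C = tr$tpE2D, G = mr)); P["F", "F"] <- res("F")
  }
  P["G", "G"] <- 1
  P
}

#' Discount factor for a model cycle
#'
#' Cycle 0 is never discounted. `"per_cycle_continuous"` compounds within
#' the year, `(1+d)^(-cycle/12)`; `"annual_step"` keeps the factor constant
#' across each model year, `(1+d)^(-floor(cycle/12))`.
#'
#' @param cycle Cycle index (0-based); may be a vector.
#' @param settings Run settings ([model_settings()]).
#' @return Discount factor(s) in `(0, 1]`.
#' @export
discount_factor <- function(cycle, settings) {
  d <- settings$discount_rate
  cpy <- settings$cycles_per_year
  if (settings$discount_convention == "annual_step")
    (1 + d)^(-(cycle %/% cpy))
  else
    (1 + d)^(-cycle / cpy)
}

# annual utility of each expanded state under a scenario
state_utilities_annual <- function(states, arm, params, scenario) {
  u <- params$utilities
  vapply(states, function(s) {
    if (s == "G") return(0)
    depression <- s %in% c("A", "C", "D")
    if (depression) {
      if (arm == "ect" && s %in% c("A", "C") &&
          !is.na(scenario$u_ect_treatment))
        return(scenario$u_ect_treatment)
      return(u$annual_depression)
    }
    enhanced <- s == "E" || (arm == "esk" && s != "E")
    if (enhanced && !is.na(scenario$u_enhanced_remission))
      return(scenario$u_enhanced_remission)
    u$annual_remission
  }, numeric(1))
}

# age-band lookup for remission mortality; errors beyond the last band
band_mortality <- function(age, remission_mortality) {
  starts <- as.numeric(names(remission_mortality))
  i <- findInterval(age, starts)
  if (i < 1 || age > starts[length(starts)] + 4.999)
    stop("age ", age, " outside the remission-mortality band table; ",
         "extend transitions$remission_mortality before lengthening the horizon")
  remission_mortality[[i]]
}

#' Run the Markov cohort model for one arm
#'
#' Iterates the cohort recursion over the expanded state space for the
#' configured horizon, accruing per-cycle costs (under the run's
#' perspective) and QALYs, both discounted. The whole cohort starts in
#' state A (depressed). Mortality, retirement status and the age band of
#' the cost table follow the cohort's current age,
#' `start_age + floor(cycle/12)`.
#'
#' @param settings Run settings ([model_settings()]).
#' @param params Parameter bundle ([trd_parameters()]).
#' @param scenario Scenario modifications ([scenario_mods()]).
#' @return A list of class `trd_arm_result`: `total_cost`, `total_qaly`
#'   (discounted), `occupancy` (matrix, cycles+1 rows including the final
#'   post-transition distribution), `trace` (per-cycle data frame with
#'   undiscounted and discounted cost/QALY streams), and `settings`.
#' @export
run_cohort <- function(settings, params = trd_parameters(),
                       scenario = scenario_mods()) {
  v <- validate_parameters(params)
  if (length(v)) stop("invalid parameters:\n  ", paste(v, collapse = "\n  "))
  if (!is.na(scenario$horizon_years))
    settings$horizon_years <- scenario$horizon_years
  if (!is.na(scenario$discount_rate))
    settings$discount_rate <- scenario$discount_rate
  arm <- settings$arm; variant <- settings$variant
  states <- expanded_states(arm, variant)
  ns <- length(states)
  n_cycles <- round(settings$horizon_years * settings$cycles_per_year)
  u_cycle_of <- function() {
    ua <- state_utilities_annual(states, arm, params, scenario)
    if (isTRUE(params$utilities$use_rounded_cycle)) {
      base <- ifelse(states %in% c("A", "C", "D"), 0.05,
                     ifelse(states == "G", 0, 0.07))
      # rounded per-cycle values only stand in for unmodified base utilities
      ifelse(ua %in% c(params$utilities$annual_depression,
                       params$utilities$annual_remission) | ua == 0,
             base, ua / settings$cycles_per_year)
    } else ua / settings$cycles_per_year
  }
  u_cycle <- u_cycle_of()
  occ <- matrix(NA_real_, n_cycles + 1, ns, dimnames = list(NULL, states))
  x <- stats::setNames(numeric(ns), states); x["A"] <- 1
  occ[1, ] <- x
  cost_cycle <- qaly_cycle <- dfac <- numeric(n_cycles)
  age_at <- function(t) settings$start_age + t %/% settings$cycles_per_year
  # per-age cost vectors are reused across the 12 cycles of a model year
  cost_vec <- function(age) vapply(states, state_cycle_cost, numeric(1),
    arm = arm, variant = variant, age = age,
    perspective = settings$perspective, params = params,
    prod_mult = scenario$prod_mult, ect_sessions = scenario$ect_sessions,
    esk_indefinite = scenario$esk_indefinite)
  P_cache <- list(); c_cache <- list()
  for (t in seq_len(n_cycles) - 1L) {
    age <- age_at(t)
    key <- as.character(age)
    if (is.null(P_cache[[key]])) {
      mr <- band_mortality(age, params$transitions$remission_mortality)
      P_cache[[key]] <- transition_matrix(arm, variant, mr, params, scenario)
      c_cache[[key]] <- cost_vec(age)
    }
    x_next <- as.vector(x %*% P_cache[[key]])
    occ_for_accrual <- if (settings$half_cycle_correction)
      0.5 * (x + x_next) else x
    dfac[t + 1] <- discount_factor(t, settings)
    cost_cycle[t + 1] <- sum(occ_for_accrual * c_cache[[key]])
    qaly_cycle[t + 1] <- sum(occ_for_accrual * u_cycle)
    x <- stats::setNames(x_next, states)
    occ[t + 2, ] <- x
  }
  trace <- data.frame(cycle = seq_len(n_cycles) - 1L,
                      age = vapply(seq_len(n_cycles) - 1L, age_at, numeric(1)),
                      cost = cost_cycle, qaly = qaly_cycle,
                      discount = dfac,
                      disc_cost = cost_cycle * dfac,
                      disc_qaly = qaly_cycle * dfac)
  structure(list(total_cost = sum(trace$disc_cost),
                 total_qaly = sum(trace$disc_qaly),
                 occupancy = occ, trace = trace, settings = settings,
                 scenario = scenario),
            class = "trd_arm_result")
}

#' @export
print.trd_arm_result <- function(x, ...) {
  s <- x$settings
  cat(sprintf("<trd_arm_result> %s arm, %s model, %s perspective\n",
              s$arm, s$variant, s$perspective))
  cat(sprintf("  horizon %g y, discount %.3g%% (%s)\n", s$horizon_years,
              100 * s$discount_rate, s$discount_convention))
  cat(sprintf("  discounted totals: cost %s GBP, %.3f QALY\n",
              format(round(x$total_cost), big.mark = ","), x$total_qaly))
  invisible(x)
}

#' Flatten a cohort run into a long per-cycle trace
#'
#' @param result A `trd_arm_result`.
#' @return Data frame with columns `cycle`, `age`, `state`, `occupancy`,
#'   `cycle_cost`, `cycle_qaly`, `discount`.
#' @export
cohort_trace <- function(result) {
  occ <- result$occupancy
  n <- nrow(result$trace)
  states <- colnames(occ)
  data.frame(
    cycle = rep(result$trace$cycle, times = length(states)),
    age = rep(result$trace$age, times = length(states)),
    state = rep(states, each = n),
    occupancy = as.vector(occ[seq_len(n), ]),
    cycle_cost = rep(result$trace$cost, times = length(states)),
    cycle_qaly = rep(result$trace$qaly, times = length(states)),
    discount = rep(result$trace$discount, times = length(states)),
    stringsAsFactors = FALSE)
}
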