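#' Monthly payroll tax on a gross wage
#'
#' 12% levied on the slice of monthly income inside the taxable band
#' (702.01 to 3863 GBP/month by default).
#'
#' @param gross Gross monthly wage, GBP.
#' @param wages Wage inputs (`trd_parameters()$wages`).
#' @return Payroll tax, GBP/month.
#' @export
#' @examples
#' payroll_tax(2340)  # full-time average wage
payroll_tax <- function(gross, wages = trd_parameters()$wages) {
  stopifnot(all(gross >= 0))
  wages$payroll_tax_rate *
    pmax(0, pmin(gross, wages$payroll_band_high) - wages$payroll_band_low)
}

#' Per-cycle productivity loss by health-state class
#'
#' Human-capital valuation at the general (average) wage rate plus payroll
#' tax. In the depression states the loss is weighted for the unemployed
#' fraction (full loss) and the part-time fraction (difference between
#' full-time and part-time value); in remission only the unemployed fraction
#' counts. Productivity loss is zero from the retirement age onwards.
#'
#' @param state_class `"depression"` or `"remission"`.
#' @param age Current age in years.
#' @param wages,employment Parameter sections from [trd_parameters()].
#' @return GBP per 30-day cycle.
#' @export
productivity_loss <- function(state_class = c("depression", "remission"), age,
                              wages = trd_parameters()$wages,
                              employment = trd_parameters()$employment) {
  state_class <- match.arg(state_class)
  if (age >= wages$retirement_age) return(0)
  v_ft <- wages$fulltime_wage + payroll_tax(wages$fulltime_wage, wages)
  v_pt <- wages$parttime_wage + payroll_tax(wages$parttime_wage, wages)
  if (state_class == "depression")
    employment$depression_unemployed * v_ft +
      employment$depression_parttime * (v_ft - v_pt)
  else
    employment$remission_unemployed * v_ft
}

#' Cost-table components for one entry
#'
#' Decomposes a cost-table row into direct healthcare, travel, informal care
#' and (age-dependent) productivity loss. The 65-plus societal total is
#' treated as authoritative "societal minus productivity"; informal care is
#' its residual after direct and travel costs.
#'
#' @param entry Cost-table entry name (e.g. `"ect_acute"`, `"state_d"`).
#' @param age Current age in years.
#' @param params Parameter bundle.
#' @return Named list with `direct`, `travel`, `informal`, `productivity`,
#'   `societal` (their sum) and `healthcare` (direct only).
#' @export
cost_components <- function(entry, age, params = trd_parameters()) {
  row <- params$cost_table[params$cost_table$entry == entry, ]
  if (nrow(row) != 1) stop("unknown cost-table entry: ", entry)
  travel <- row$n_visits * params$unit_costs$travel_per_visit
  informal <- row$total_ge65 - row$direct - travel
  prod <- productivity_loss(row$class, age, params$wages, params$employment)
  list(direct = row$direct, travel = travel, informal = informal,
       productivity = prod,
       societal = row$direct + travel + informal + prod,
       healthcare = row$direct)
}

#' Re-derive and check the direct/informal/travel split of the cost table
#'
#' Recomputes the informal-care residual for every cost-table entry (65-plus
#' total minus direct minus travel) and errors if any override makes it
#' negative. Returns the component decomposition for inspection or export.
#'
#' @param params Parameter bundle (possibly with overridden `direct` or
#'   `n_visits` columns).
#' @return Data frame with one row per cost-table entry and columns `entry`,
#'   `class`, `direct`, `travel`, `informal`, `productivity_lt65`,
#'   `total_lt65`, `total_ge65`.
#' @export
calibrate_direct_costs <- function(params = trd_parameters()) {
  ct <- params$cost_table
  travel <- ct$n_visits * params$unit_costs$travel_per_visit
  informal <- ct$total_ge65 - ct$direct - travel
  if (any(informal < -1e-9))
    stop("negative informal-care residual for: ",
         paste(ct$entry[informal < -1e-9], collapse = ", "),
         " (direct + travel exceed the 65-plus total)")
  prod <- vapply(seq_len(nrow(ct)), function(i)
    productivity_loss(ct$class[i], age = params$wages$retirement_age - 1,
                      params$wages, params$employment), numeric(1))
  data.frame(entry = ct$entry, class = ct$class, direct = ct$direct,
             travel = travel, informal = informal, productivity_lt65 = prod,
             total_lt65 = ct$total_lt65, total_ge65 = ct$total_ge65,
             stringsAsFactors = FALSE)
}

#' Per-cycle cost delta when the ECT session frequency changes
#'
#' The base schedule is 8 sessions per treatment cycle; sensitivity scenarios
#' use 6 or 12. Each added/removed session changes the direct cost by one
#' session fee and, under the societal perspective, one travel fare.
#'
#' @param n_sessions Sessions per treatment cycle (>= 1).
#' @param perspective `"societal"` or `"healthcare"`.
#' @param unit_costs Unit-cost inputs.
#' @return GBP per cycle, added to states A and C of the ECT arm.
#' @export
ect_frequency_delta <- function(n_sessions,
                                perspective = c("societal", "healthcare"),
                                unit_costs = trd_parameters()$unit_costs) {
  perspective <- match.arg(perspective)
  stopifnot(n_sessions >= 1)
  per_session <- unit_costs$ect_session +
    if (perspective == "societal") unit_costs$travel_per_visit else 0
  (n_sessions - 8) * per_session
}

#' Per-cycle cost of an expanded model state
#'
#' Maps an expanded engine state to its cost-table entry and returns the
#' per-cycle cost under the requested perspective, age band and scenario
#' modifications. Death costs nothing.
#'
#' @param state Expanded state label (`"A"`, `"B"`, `"B1"`..., `"C"`, `"D"`,
#'   `"E"`, `"F"`, `"G"`).
#' @param arm,variant Treatment arm and model variant (see
#'   [model_settings()]).
#' @param age Current age in years.
#' @param perspective `"societal"` or `"healthcare"`.
#' @param params Parameter bundle.
#' @param prod_mult Multiplier on the productivity-loss component
#'   (sensitivity scenario 1).
#' @param ect_sessions ECT sessions per treatment cycle (scenario 2).
#' @param esk_indefinite Esketamine maintenance continues indefinitely at
#'   the month-2-to-5 cost (scenario 8).
#' @return GBP per cycle.
#' @export
state_cycle_cost <- function(state, arm, variant, age,
                             perspective = c("societal", "healthcare"),
                             params = trd_parameters(), prod_mult = 1,
                             ect_sessions = 8, esk_indefinite = FALSE) {
  perspective <- match.arg(perspective)
  entry <- state_cost_entry(state, arm, variant, esk_indefinite)
  if (is.na(entry)) return(0)  # death
  comp <- cost_components(entry, age, params)
  extra <- if (state %in% c("A", "C") && arm == "ect")
    ect_frequency_delta(ect_sessions, perspective, params$unit_costs) else 0
  if (perspective == "healthcare") return(comp$healthcare + extra)
  comp$direct + comp$travel + comp$informal +
    prod_mult * comp$productivity + extra
}

# expanded state -> cost-table entry (NA for death)
state_cost_entry <- function(state, arm, variant, esk_indefinite = FALSE) {
  if (state == "G") return(NA_character_)
  if (arm == "ect") {
    switch(state,
      A = "ect_acute", C = "ect_acute",
      B = "b_standard",
      B1 = "mect_month1", B2p = "mect_ongoing",
      D = "state_d", E = "b_standard",
      stop("state ", state, " is not part of the ", arm, "/", variant,
           " configuration"))
  } else {
    if (state %in% c("A", "C")) return("esk_acute")
    if (state == "B1") return("esk_month1")
    if (state %in% c("B2", "B3", "B4", "B5")) return("esk_month2to5")
    if (state == "B6")
      return(if (esk_indefinite) "esk_month2to5" else "esk_month6")
    if (state == "D") return("state_d")
    if (state %in% c("E", "F")) return("b_standard")
    stop("state ", state, " is not part of the esketamine configuration")
  }
}

#' Export the full cost table with its component split
#'
#' Wide export of [calibrate_direct_costs()] suitable for `write.csv()`:
#' one row per (entry, age band) with the component decomposition and the
#' perspective totals.
#'
#' @param params Parameter bundle.
#' @return Data frame.
#' @export
export_cost_table <- function(params = trd_parameters()) {
  split <- calibrate_direct_costs(params)
  young <- transform(split, age_band = "<65",
                     societal = direct + travel + informal + productivity_lt65,
                     healthcare = direct)
  old <- transform(split, age_band = ">=65", productivity_lt65 = 0,
                   societal = direct + travel + informal,
                   healthcare = direct)
  out <- rbind(young, old)
  names(out)[names(out) == "productivity_lt65"] <- "productivity"
  out[order(out$entry, out$age_band), ]
}
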