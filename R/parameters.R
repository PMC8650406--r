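#' Default model parameters
#'
#' Returns the complete parameter bundle of the cost-utility model: per-cycle
#' transition probabilities, age-banded remission mortality, annual utilities,
#' wage and employment inputs for the human-capital productivity-loss formula,
#' unit costs, and the per-state per-cycle cost table (societal totals for the
#' under-65 and 65-plus age bands, plus the direct-cost component used by the
#' healthcare perspective).
#'
#' All monetary values are 2019 GBP. Transition probabilities are per 30-day
#' cycle; the printed per-cycle values are authoritative model inputs (the
#' rate-conversion helpers in [rescale_prob()] reproduce them from their
#' source-trial summaries, but the engine never re-derives them silently).
#'
#' The direct-cost split of the state cost table is not fully identified by
#' the societal totals; the defaults ship a documented calibration (see the
#' package vignette) in which intensive-treatment states carry their full
#' non-travel cost as direct healthcare cost, standard-treatment states carry
#' a GP-visit-plus-antidepressant direct cost, and informal care absorbs the
#' remainder. Every entry can be overridden and re-checked with
#' [calibrate_direct_costs()].
#'
#' @return A list of class `trd_params` with elements `transitions`,
#'   `utilities`, `wages`, `employment`, `unit_costs`, `cost_table`.
#' @seealso [validate_parameters()], [load_config()], [model_settings()]
#' @export
#' @examples
#' p <- trd_parameters()
#' p$transitions$tpA2B_ect
#' subset(p$cost_table, entry == "state_d")$total_lt65
trd_parameters <- function() {
  p <- list(
    transitions = list(
      # remission on one 30-day treatment cycle (states A and C)
      tpA2B_ect = 0.696,
      tpA2B_esk = 0.392,
      # relapse per cycle from remission, by maintenance regimen
      tpB2C_ect  = 0.108,
      tpB2C_mect = 0.0300,
      tpB2C_esk  = 0.0724,
      # standard-treatment remission/relapse (states D and E) and
      # depression mortality (states A, C, D)
      tpD2E   = 0.107,
      tpE2D   = 0.232,
      tpDep2G = 0.00304,
      # lifetable mortality per cycle while in remission, 5-year age bands
      remission_mortality = c(
        "45" = 0.000180, "50" = 0.000265, "55" = 0.000407, "60" = 0.000646,
        "65" = 0.00100,  "70" = 0.00163,  "75" = 0.00285)
    ),
    utilities = list(
      annual_remission  = 0.81,
      annual_depression = 0.57,
      # per-cycle utilities are annual/12 by default; TRUE uses the
      # display-rounded 0.07/0.05 per-cycle values instead
      use_rounded_cycle = FALSE
    ),
    wages = list(
      fulltime_wage    = 2340,
      parttime_wage    = 680,
      payroll_tax_rate = 0.12,
      payroll_band_low = 702.01,
      payroll_band_high = 3863,
      retirement_age   = 65
    ),
    employment = list(
      depression_unemployed = 0.54,
      depression_parttime   = 0.13,
      remission_unemployed  = 0.23
    ),
    unit_costs = list(
      ect_session        = 558,
      esketamine_per_28mg = 163,
      travel_per_visit   = 18.80,
      gp_visit           = 39,
      psychiatrist_visit = 170,
      nurse_visit        = 12
    ),
    # Societal per-cycle totals by age band as printed; `direct` is the
    # calibrated direct-healthcare component; `n_visits` counts CMHT/ECT
    # attendances per cycle (travel = n_visits * travel_per_visit, societal
    # perspective only). Informal care is the residual
    # total_ge65 - direct - travel. `class` drives utility and productivity.
    cost_table = data.frame(
      entry = c("ect_acute", "esk_acute", "b_standard", "mect_month1",
                "mect_ongoing", "esk_month1", "esk_month2to5", "esk_month6",
                "state_d"),
      class = c("depression", "depression", "remission", "remission",
                "remission", "remission", "remission", "remission",
                "depression"),
      total_lt65 = c(7932, 7210, 701, 3313, 2161, 2882, 1583, 1890, 2729),
      total_ge65 = c(6321, 5599, 118, 2730, 1578, 2299, 1000, 1307, 1119),
      direct   = c(6170.6, 5004.8, 49, 2654.8, 1540.4, 2223.8, 962.4,
                   1288.2, 580.4),
      n_visits = c(8, 8, 0, 4, 2, 4, 2, 1, 0),
      stringsAsFactors = FALSE
    )
  )
  class(p) <- "trd_params"
  p
}

#' Model run settings
#'
#' @param arm `"ect"` or `"esk"` (intranasal esketamine).
#' @param variant `"main"` (no maintenance ECT) or `"maintenance"` (remitters
#'   on ECT receive ongoing maintenance ECT).
#' @param perspective `"societal"` (direct + productivity loss + informal
#'   care + travel) or `"healthcare"` (direct costs only).
#' @param start_age Age at model entry, years.
#' @param horizon_years Model horizon in years.
#' @param cycle_days Cycle length in days.
#' @param cycles_per_year Cycles per year.
#' @param discount_rate Annual discount rate applied to costs and QALYs.
#' @param discount_convention `"per_cycle_continuous"` discounts every cycle
#'   at `(1+d)^(-cycle/12)`; `"annual_step"` holds the factor constant within
#'   each model year at `(1+d)^(-floor(cycle/12))`.
#' @param half_cycle_correction Apply a half-cycle correction to the accrual
#'   streams (off by default, the spreadsheet-model convention).
#' @return A list of class `trd_settings`.
#' @export
model_settings <- function(arm = c("ect", "esk"),
                           variant = c("main", "maintenance"),
                           perspective = c("societal", "healthcare"),
                           start_age = 45, horizon_years = 35,
                           cycle_days = 30, cycles_per_year = 12,
                           discount_rate = 0.035,
                           discount_convention = c("per_cycle_continuous",
                                                   "annual_step"),
                           half_cycle_correction = FALSE) {
  s <- list(arm = match.arg(arm), variant = match.arg(variant),
            perspective = match.arg(perspective), start_age = start_age,
            horizon_years = horizon_years, cycle_days = cycle_days,
            cycles_per_year = cycles_per_year, discount_rate = discount_rate,
            discount_convention = match.arg(discount_convention),
            half_cycle_correction = isTRUE(half_cycle_correction))
  class(s) <- "trd_settings"
  stopifnot(s$discount_rate >= 0, s$discount_rate < 1,
            s$horizon_years > 0, s$cycle_days > 0,
            s$start_age + s$horizon_years <= 120)
  s
}

#' Validate a parameter bundle
#'
#' Checks every type invariant (probabilities and fractions in `[0, 1]`,
#' per-state exit probabilities summing below 1, non-decreasing remission
#' mortality, wage band ordering, non-negative costs, cost-component
#' consistency) and reports violations rather than raising.
#'
#' @param params A `trd_params` bundle.
#' @return Character vector of violation messages; empty if the bundle is
#'   valid.
#' @export
validate_parameters <- function(params) {
  v <- character()
  bad <- function(msg) v <<- c(v, msg)
  tr <- params$transitions
  probs <- c(tpA2B_ect = tr$tpA2B_ect, tpA2B_esk = tr$tpA2B_esk,
             tpB2C_ect = tr$tpB2C_ect, tpB2C_mect = tr$tpB2C_mect,
             tpB2C_esk = tr$tpB2C_esk, tpD2E = tr$tpD2E, tpE2D = tr$tpE2D,
             tpDep2G = tr$tpDep2G, tr$remission_mortality)
  out <- probs < 0 | probs > 1
  for (nm in names(probs)[out])
    bad(sprintf("%s: probability out of [0,1] (%g)", nm, probs[[nm]]))
  # exit-probability mass per depression/remission state must leave room
  # for the residual transition
  exits <- c(A_ect = tr$tpA2B_ect + tr$tpDep2G,
             A_esk = tr$tpA2B_esk + tr$tpDep2G,
             D = tr$tpD2E + tr$tpDep2G,
             E = tr$tpE2D + max(tr$remission_mortality),
             B_ect = tr$tpB2C_ect + max(tr$remission_mortality),
             B_mect = tr$tpB2C_mect + max(tr$remission_mortality),
             B_esk = tr$tpB2C_esk + max(tr$remission_mortality))
  for (nm in names(exits)[exits > 1 + 1e-12])
    bad(sprintf("%s: exit probabilities sum to %g > 1", nm, exits[[nm]]))
  if (is.unsorted(tr$remission_mortality))
    bad("remission_mortality: not non-decreasing in age band")
  u <- params$utilities
  if (!(u$annual_depression >= 0 && u$annual_depression <= u$annual_remission &&
        u$annual_remission <= 1))
    bad("utilities: need 0 <= depression <= remission <= 1")
  w <- params$wages
  if (w$payroll_band_low >= w$payroll_band_high)
    bad("wages: payroll_band_low must be below payroll_band_high")
  if (w$fulltime_wage < 0 || w$parttime_wage < 0)
    bad("wages: wages must be non-negative")
  e <- params$employment
  fr <- unlist(e)
  for (nm in names(fr)[fr < 0 | fr > 1])
    bad(sprintf("employment$%s: fraction out of [0,1]", nm))
  if (e$depression_unemployed + e$depression_parttime > 1)
    bad("employment: depression_unemployed + depression_parttime exceed 1")
  uc <- unlist(params$unit_costs)
  for (nm in names(uc)[uc < 0])
    bad(sprintf("unit_costs$%s: negative cost", nm))
  ct <- params$cost_table
  if (any(ct$total_lt65 < ct$total_ge65 - 1e-9))
    bad("cost_table: total_lt65 below total_ge65")
  informal <- ct$total_ge65 - ct$direct -
    ct$n_visits * params$unit_costs$travel_per_visit
  for (i in which(informal < -1e-9))
    bad(sprintf("cost_table$%s: direct + travel exceed the 65-plus total",
                ct$entry[i]))
  v
}

## ---- configuration files ---------------------------------------------------

#' Save / load a parameter bundle as a YAML configuration file
#'
#' The file mirrors the bundle's nested structure; the cost table is stored
#' as one mapping per state entry. [load_config()] starts from
#' [trd_parameters()] and overlays whatever the file provides, so a partial
#' file overrides just the named fields; unknown fields raise a warning
#' naming them. A packaged copy of the full defaults ships as
#' `system.file("extdata", "table1.yaml", package = "trdcea")`.
#'
#' @param params A `trd_params` bundle.
#' @param path File path to write/read.
#' @return `load_config()` returns a validated `trd_params` bundle;
#'   `save_config()` returns `path` invisibly.
#' @export
save_config <- function(params, path) {
  x <- unclass(params)
  ct <- x$cost_table
  x$cost_table <- lapply(seq_len(nrow(ct)), function(i) as.list(ct[i, ]))
  x$transitions$remission_mortality <- as.list(x$transitions$remission_mortality)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  params <- trd_parameters()
  overlay <- function(base, new, where) {
    for (nm in names(new)) {
      if (!nm %in% names(base)) {
        warning("unknown config field: ", where, nm, call. = FALSE)
        next
      }
      if (is.list(new[[nm]]) && is.list(base[[nm]]) &&
          !is.data.frame(base[[nm]]))
        base[[nm]] <- overlay(base[[nm]], new[[nm]], paste0(where, nm, "$"))
      else base[[nm]] <- new[[nm]]
    }
    base
  }
  for (sec in setdiff(names(raw), c("cost_table", "transitions"))) {
    if (!sec %in% names(params)) {
      warning("unknown config field: ", sec, call. = FALSE)
      next
    }
    params[[sec]] <- overlay(params[[sec]], raw[[sec]], paste0(sec, "$"))
  }
  if (!is.null(raw$transitions)) {
    tr <- raw$transitions
    if (!is.null(tr$remission_mortality)) {
      rm_ <- unlist(tr$remission_mortality)
      if (is.null(names(rm_)) || any(names(rm_) == ""))
        stop("transitions$remission_mortality entries must be named by age band")
      tr$remission_mortality <- rm_
    }
    params$transitions <- overlay(params$transitions, tr, "transitions$")
  }
  if (!is.null(raw$cost_table)) {
    rows <- raw$cost_table
    need <- c("entry", "class", "total_lt65", "total_ge65", "direct", "n_visits")
    for (row in rows) {
      miss <- setdiff(need, names(row))
      if (length(miss))
        stop("cost_table entry missing field(s): ", paste(miss, collapse = ", "))
    }
    params$cost_table <- do.call(rbind, lapply(rows, function(row)
      data.frame(row[need], stringsAsFactors = FALSE)))
  }
  v <- validate_parameters(params)
  if (length(v)) stop("invalid configuration:\n  ", paste(v, collapse = "\n  "))
  params
}

#' @export
print.trd_params <- function(x, ...) {
  cat("<trd_params> cost-utility model inputs (2019 GBP, 30-day cycles)\n")
  cat(sprintf("  remission/cycle: ECT %.3g, esketamine %.3g; relapse/cycle: %.3g / %.3g (M-ECT %.3g)\n",
              x$transitions$tpA2B_ect, x$transitions$tpA2B_esk,
              x$transitions$tpB2C_ect, x$transitions$tpB2C_esk,
              x$transitions$tpB2C_mect))
  cat(sprintf("  annual utilities: remission %.2f, depression %.2f\n",
              x$utilities$annual_remission, x$utilities$annual_depression))
  cat(sprintf("  cost table: %d state entries\n", nrow(x$cost_table)))
  invisible(x)
}
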