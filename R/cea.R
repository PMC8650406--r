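#' Incremental cost-effectiveness of ECT versus a comparator arm
#'
#' Computes incremental cost and QALYs, the ICER where it is defined
#' (deltas of the same sign, non-zero QALY difference), the dominance
#' verdict, and cost-effectiveness at the NICE willingness-to-pay bounds
#' (net-monetary-benefit rule, which handles every quadrant of the
#' cost-effectiveness plane).
#'
#' @param ect `trd_arm_result` for the ECT arm.
#' @param cmp `trd_arm_result` for the comparator (esketamine) arm, run
#'   under identical settings except the arm.
#' @param threshold_low,threshold_high Willingness-to-pay bounds,
#'   GBP per QALY.
#' @return A list of class `trd_ce_result` with the per-arm totals, deltas,
#'   `icer`, `verdict` (`"ect_dominates"`, `"comparator_dominates"` or
#'   `"icer"`), and logical `cost_effective_low`/`cost_effective_high`.
#' @export
incremental <- function(ect, cmp, threshold_low = 20000,
                        threshold_high = 30000) {
  se <- ect$settings; sc <- cmp$settings
  same <- c("variant", "perspective", "start_age", "horizon_years",
            "cycle_days", "cycles_per_year", "discount_rate",
            "discount_convention", "half_cycle_correction")
  for (f in same)
    if (!identical(se[[f]], sc[[f]]))
      stop("arm results differ in settings field '", f, "'")
  if (identical(se$arm, sc$arm)) stop("both results come from the same arm")
  delta_cost <- ect$total_cost - cmp$total_cost
  delta_qaly <- ect$total_qaly - cmp$total_qaly
  eps <- 1e-9
  verdict <- if (delta_cost <= eps && delta_qaly >= -eps &&
                 (delta_cost < -eps || delta_qaly > eps)) "ect_dominates"
  else if (delta_cost >= -eps && delta_qaly <= eps &&
           (delta_cost > eps || delta_qaly < -eps)) "comparator_dominates"
  else "icer"
  icer <- if (verdict == "icer" && abs(delta_qaly) > eps &&
              sign(delta_cost) == sign(delta_qaly)) delta_cost / delta_qaly
  else NA_real_
  structure(list(
    cost_ect = ect$total_cost, qaly_ect = ect$total_qaly,
    cost_cmp = cmp$total_cost, qaly_cmp = cmp$total_qaly,
    delta_cost = delta_cost, delta_qaly = delta_qaly,
    icer = icer, verdict = verdict,
    cost_effective_low = threshold_low * delta_qaly - delta_cost >= -eps,
    cost_effective_high = threshold_high * delta_qaly - delta_cost >= -eps,
    threshold_low = threshold_low, threshold_high = threshold_high),
    class = "trd_ce_result")
}

#' @export
print.trd_ce_result <- function(x, ...) {
  cat("<trd_ce_result>\n")
  cat(sprintf("  ECT: %s GBP / %.2f QALY; comparator: %s GBP / %.2f QALY\n",
              format(round(x$cost_ect), big.mark = ","), x$qaly_ect,
              format(round(x$cost_cmp), big.mark = ","), x$qaly_cmp))
  cat(sprintf("  incremental: %s GBP / %.2f QALY -> %s\n",
              format(round(x$delta_cost), big.mark = ","), x$delta_qaly,
              if (x$verdict == "icer")
                paste0("ICER ", format(round(x$icer), big.mark = ","),
                       " GBP/QALY")
              else x$verdict))
  invisible(x)
}

#' Catalogue of deterministic sensitivity-analysis scenarios
#'
#' One entry per printed sensitivity row plus the base case under both
#' perspectives: productivity loss doubled/halved (1a/1b, societal only —
#' healthcare totals are invariant), ECT 6 or 12 sessions per cycle
#' (2a-2d), esketamine remission raised to 0.5 (3a/3b), ECT remission
#' lowered to 0.5 (4a/4b), second-treatment remission raised to 0.9 in both
#' arms (5a/5b), a five-year horizon (6a/6b), utility 0.3 during ECT
#' treatment with 0.85 for remission after esketamine or on standard
#' treatment (7a/7b), esketamine maintained for as long as remission lasts
#' (8a/8b), and no discounting (9a/9b).
#'
#' @param variant `"main"` or `"maintenance"` (the catalogue is identical;
#'   the variant is recorded in each entry).
#' @return Named list of entries, each with `id`, `description`,
#'   `perspective`, `variant` and `mods` (a [scenario_mods()]).
#' @export
scenario_catalog <- function(variant = c("main", "maintenance")) {
  variant <- match.arg(variant)
  mk <- function(id, description, perspective, mods = scenario_mods())
    list(id = id, description = description, perspective = perspective,
         variant = variant, mods = mods)
  entries <- list(
    mk("base-societal", "Base case - societal", "societal"),
    mk("base-healthcare", "Base case - healthcare", "healthcare"),
    mk("1a", "Doubling the productivity loss", "societal",
       scenario_mods(prod_mult = 2)),
    mk("1b", "Halving the productivity loss", "societal",
       scenario_mods(prod_mult = 0.5)),
    mk("2a", "ECT six times per cycle - societal", "societal",
       scenario_mods(ect_sessions = 6)),
    mk("2b", "ECT six times per cycle - healthcare", "healthcare",
       scenario_mods(ect_sessions = 6)),
    mk("2c", "ECT 12 times per cycle - societal", "societal",
       scenario_mods(ect_sessions = 12)),
    mk("2d", "ECT 12 times per cycle - healthcare", "healthcare",
       scenario_mods(ect_sessions = 12)),
    mk("3a", "Esketamine remission raised to 0.5 - societal", "societal",
       scenario_mods(tp = list(tpA2B_esk = 0.5))),
    mk("3b", "Esketamine remission raised to 0.5 - healthcare", "healthcare",
       scenario_mods(tp = list(tpA2B_esk = 0.5))),
    mk("4a", "ECT remission lowered to 0.5 - societal", "societal",
       scenario_mods(tp = list(tpA2B_ect = 0.5))),
    mk("4b", "ECT remission lowered to 0.5 - healthcare", "healthcare",
       scenario_mods(tp = list(tpA2B_ect = 0.5))),
    mk("5a", "Second-treatment remission raised to 0.9 - societal",
       "societal", scenario_mods(tp = list(tpC2B_ect = 0.9,
                                           tpC2B_esk = 0.9))),
    mk("5b", "Second-treatment remission raised to 0.9 - healthcare",
       "healthcare", scenario_mods(tp = list(tpC2B_ect = 0.9,
                                             tpC2B_esk = 0.9))),
    mk("6a", "Five-year time horizon - societal", "societal",
       scenario_mods(horizon_years = 5)),
    mk("6b", "Five-year time horizon - healthcare", "healthcare",
       scenario_mods(horizon_years = 5)),
    mk("7a", "Utility 0.3 during ECT, 0.85 post-esketamine/AD remission - societal",
       "societal", scenario_mods(u_ect_treatment = 0.3,
                                 u_enhanced_remission = 0.85)),
    mk("7b", "Utility 0.3 during ECT, 0.85 post-esketamine/AD remission - healthcare",
       "healthcare", scenario_mods(u_ect_treatment = 0.3,
                                   u_enhanced_remission = 0.85)),
    mk("8a", "Esketamine for as long as remission lasts - societal",
       "societal", scenario_mods(esk_indefinite = TRUE)),
    mk("8b", "Esketamine for as long as remission lasts - healthcare",
       "healthcare", scenario_mods(esk_indefinite = TRUE)),
    mk("9a", "No discounting - societal", "societal",
       scenario_mods(discount_rate = 0)),
    mk("9b", "No discounting - healthcare", "healthcare",
       scenario_mods(discount_rate = 0))
  )
  stats::setNames(entries, vapply(entries, `[[`, "", "id"))
}

#' Run one catalogued scenario (both arms) and compare
#'
#' @param entry One element of [scenario_catalog()].
#' @param params Parameter bundle.
#' @param base_settings Settings template; arm/variant/perspective are taken
#'   from the entry.
#' @return A `trd_ce_result`.
#' @export
run_scenario <- function(entry, params = trd_parameters(),
                         base_settings = model_settings()) {
  one <- function(arm) {
    s <- base_settings
    s$arm <- arm; s$variant <- entry$variant
    s$perspective <- entry$perspective
    run_cohort(s, params, entry$mods)
  }
  incremental(one("ect"), one("esk"))
}

#' Regenerate the full cost-effectiveness table for a model variant
#'
#' Base case plus every sensitivity scenario, one row per printed table row:
#' per-arm discounted cost and QALYs, increments, ICER or dominance verdict.
#'
#' @param variant `"main"` or `"maintenance"`.
#' @param params Parameter bundle.
#' @param base_settings Settings template (discount convention, horizon,
#'   half-cycle flag...).
#' @param rounded Round costs to whole GBP and QALYs to 2 d.p. for display.
#' @return Data frame with one row per scenario/perspective.
#' @export
run_table <- function(variant = c("main", "maintenance"),
                      params = trd_parameters(),
                      base_settings = model_settings(), rounded = FALSE) {
  variant <- match.arg(variant)
  cat_ <- scenario_catalog(variant)
  rows <- lapply(cat_, function(entry) {
    ce <- run_scenario(entry, params, base_settings)
    data.frame(id = entry$id, description = entry$description,
               perspective = entry$perspective,
               cost_ect = ce$cost_ect, qaly_ect = ce$qaly_ect,
               cost_esk = ce$cost_cmp, qaly_esk = ce$qaly_cmp,
               delta_cost = ce$delta_cost, delta_qaly = ce$delta_qaly,
               icer = ce$icer, verdict = ce$verdict,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  if (rounded) {
    for (cc in c("cost_ect", "cost_esk", "delta_cost", "icer"))
      out[[cc]] <- round(out[[cc]])
    for (cc in c("qaly_ect", "qaly_esk", "delta_qaly"))
      out[[cc]] <- round(out[[cc]], 2)
  }
  out
}
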