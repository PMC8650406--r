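test_that("transition rows respect the model's arrows and residual-mass rule", {
  P <- transition_matrix("ect", "main", 0.000180)
  expect_equal(rowSums(P), rep(1, nrow(P)), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(P["A", "B"], 0.696)
  expect_equal(P["A", "G"], 0.00304)
  expect_equal(P["A", "D"], 1 - 0.696 - 0.00304)   # residual, = 0.30096
  expect_equal(P["B", "C"], 0.108)
  expect_equal(P["B", "G"], 0.000180)
  expect_identical(P["G", "G"], 1)                  # absorbing
  expect_true(all(P["G", colnames(P) != "G"] == 0))

  # esketamine tunnel: month m advances to month m+1, month 6 to F
  Pk <- transition_matrix("esk", "main", 0.000180)
  expect_equal(Pk["B2", "B3"], 1 - 0.0724 - 0.000180)
  expect_equal(Pk["B6", "F"], 1 - 0.0724 - 0.000180)
  expect_equal(Pk["B6", "C"], 0.0724)
  expect_equal(Pk["F", "C"], 0.232)    # relapse as on standard treatment
  expect_equal(Pk["A", "B1"], 0.392)
  # indefinite maintenance reroutes B6 onto itself; F becomes unreachable
  Pk8 <- transition_matrix("esk", "main", 0.000180,
                           scenario = scenario_mods(esk_indefinite = TRUE))
  expect_equal(Pk8["B6", "B6"], 1 - 0.0724 - 0.000180)
  expect_identical(sum(Pk8[, "F"]) - Pk8["F", "F"], 0)

  # maintenance-ECT tunnel relapses at the maintenance rate
  Pm <- transition_matrix("ect", "maintenance", 0.00100)
  expect_equal(Pm["B1", "C"], 0.0300)
  expect_equal(Pm["B1", "B2p"], 1 - 0.0300 - 0.00100)
  expect_equal(Pm["B2p", "B2p"], 1 - 0.0300 - 0.00100)

  # over-committed rows are rejected with the state named
  expect_error(
    transition_matrix("ect", "main", 0.5,
                      scenario = scenario_mods(tp = list(tpB2C_ect = 0.9))),
    "state B")
})

test_that("occupancy is conserved, non-negative, and death is monotone (random bundles)", {
  set.seed(42)
  for (i in 1:8) {
    p <- random_params()
    s <- random_settings()
    r <- run_cohort(s, p)
    expect_equal(rowSums(r$occupancy), rep(1, nrow(r$occupancy)),
                 ignore_attr = TRUE, tolerance = 1e-9)
    expect_true(all(r$occupancy >= -1e-12))
    expect_true(all(diff(r$occupancy[, "G"]) >= -1e-12))
  }
})

test_that("with mortality switched off nobody dies", {
  p <- base_params
  p$transitions$tpDep2G <- 0
  p$transitions$remission_mortality[] <- 0
  r <- run_cohort(settings_for("esk", "main"), p)
  expect_true(all(r$occupancy[, "G"] == 0))
})

test_that("degenerate certain-remission cohort matches the hand-computed QALY", {
  # one depressed cycle then 11 remission cycles, undiscounted:
  # 0.57/12 + 11 * 0.81/12 = 0.79
  p <- certain_remission_params()
  s <- settings_for("ect", "main", horizon_years = 1, discount_rate = 0)
  r <- run_cohort(s, p)
  expect_equal(r$total_qaly, 0.0475 + 11 * 0.0675, tolerance = 1e-12)
  expect_equal(r$total_qaly, 0.79, tolerance = 1e-12)
  # zero-length horizon accrues nothing
  s0 <- settings_for("ect", "main", horizon_years = 1 / 12)
  r0 <- run_cohort(s0, p)
  expect_equal(nrow(r0$trace), 1L)
})

test_that("discounted QALYs equal the analytic annuity in the certain-remission limit", {
  p <- certain_remission_params()
  s <- settings_for("ect", "main", horizon_years = 10)
  r <- run_cohort(s, p)
  g <- (1 + s$discount_rate)^(-1 / 12)
  n <- 120
  annuity <- 0.0475 + 0.0675 * g * (1 - g^(n - 1)) / (1 - g)
  expect_equal(r$total_qaly, annuity, tolerance = 1e-9)
})

test_that("discount factors follow the configured convention", {
  s_cont <- settings_for()
  s_step <- settings_for(discount_convention = "annual_step")
  expect_identical(discount_factor(0, s_cont), 1)
  expect_identical(discount_factor(0, s_step), 1)
  expect_equal(discount_factor(12, s_cont), 1 / 1.035, tolerance = 1e-12)
  expect_equal(discount_factor(12, s_step), 1 / 1.035, tolerance = 1e-12)
  expect_equal(discount_factor(6, s_cont), 1.035^(-0.5), tolerance = 1e-12)
  expect_identical(discount_factor(6, s_step), 1)   # within the first year
  s0 <- settings_for(discount_rate = 0)
  expect_identical(discount_factor(0:419, s0), rep(1, 420))
  # totals are non-increasing in the discount rate
  r0 <- run_cohort(settings_for(discount_rate = 0), base_params)
  r35 <- run_cohort(settings_for(), base_params)
  expect_gt(r0$total_cost, r35$total_cost)
  expect_gt(r0$total_qaly, r35$total_qaly)
})

test_that("totals equal the sums of the trace streams and the trace flattens cleanly", {
  r <- run_cohort(settings_for("esk", "main"), base_params)
  expect_equal(r$total_cost, sum(r$trace$disc_cost), tolerance = 1e-12)
  expect_equal(r$total_qaly, sum(r$trace$disc_qaly), tolerance = 1e-12)
  expect_equal(r$trace$disc_cost, r$trace$cost * r$trace$discount,
               tolerance = 1e-12)
  long <- cohort_trace(r)
  expect_identical(nrow(long), nrow(r$trace) * ncol(r$occupancy))
  expect_setequal(unique(long$state), expanded_states("esk", "main"))
  agg <- tapply(long$occupancy, long$cycle, sum)
  expect_equal(as.vector(agg), rep(1, nrow(r$trace)), tolerance = 1e-9)
})

test_that("the half-cycle correction shifts accrual by at most one cycle's worth", {
  s <- settings_for(half_cycle_correction = TRUE)
  r_hc <- run_cohort(s, base_params)
  r <- run_cohort(settings_for(), base_params)
  expect_false(identical(r_hc$total_qaly, r$total_qaly))
  expect_lt(abs(r_hc$total_cost - r$total_cost), max(r$trace$cost))
  expect_lt(abs(r_hc$total_qaly - r$total_qaly), max(r$trace$qaly))
})

test_that("horizons beyond the mortality band table are refused", {
  s <- settings_for(horizon_years = 40)
  expect_error(run_cohort(s, base_params), "remission-mortality band")
})
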