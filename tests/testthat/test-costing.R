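test_that("payroll tax applies 12% inside the taxable band only", {
  expect_equal(payroll_tax(2340), 0.12 * (2340 - 702.01), tolerance = 1e-9)
  expect_equal(payroll_tax(2340), 196.56, tolerance = 0.01)
  expect_identical(payroll_tax(680), 0)          # below the band
  expect_identical(payroll_tax(0), 0)
  expect_equal(payroll_tax(5000), 0.12 * (3863 - 702.01), tolerance = 1e-9)
  expect_error(payroll_tax(-1))
})

test_that("productivity loss matches the wage formula and stops at retirement", {
  expect_equal(productivity_loss("depression", 50), 1611.10, tolerance = 0.01)
  expect_equal(productivity_loss("remission", 50), 583.41, tolerance = 0.01)
  expect_identical(productivity_loss("depression", 67), 0)
  expect_identical(productivity_loss("remission", 65), 0)
})

test_that("the under/over-65 column difference equals productivity loss for every state row", {
  # printed totals are whole GBP, so compare at printed precision
  ct <- base_params$cost_table
  for (i in seq_len(nrow(ct))) {
    prod <- productivity_loss(ct$class[i], 50)
    expect_lte(abs((ct$total_lt65[i] - ct$total_ge65[i]) - round(prod)), 1)
  }
})

test_that("state cycle costs reproduce the printed table under both perspectives", {
  p <- base_params
  # societal, young: printed under-65 column (component sum, within 2 GBP)
  expect_equal(state_cycle_cost("A", "ect", "main", 50, "societal", p),
               7932, tolerance = 2 / 7932)
  expect_equal(state_cycle_cost("C", "esk", "main", 50, "societal", p),
               7210, tolerance = 2 / 7210)
  expect_equal(state_cycle_cost("D", "esk", "main", 50, "societal", p),
               2729, tolerance = 2 / 2729)
  # societal, retired: printed 65-plus column exactly
  expect_equal(state_cycle_cost("B2p", "ect", "maintenance", 70, "societal", p),
               1578, tolerance = 1e-9)
  expect_equal(state_cycle_cost("E", "esk", "main", 70, "societal", p),
               118, tolerance = 1e-9)
  expect_equal(state_cycle_cost("B6", "esk", "main", 66, "societal", p),
               1307, tolerance = 1e-9)
  # death costs nothing, any perspective
  expect_identical(state_cycle_cost("G", "ect", "main", 50, "societal", p), 0)
  expect_identical(state_cycle_cost("G", "esk", "main", 70, "healthcare", p), 0)
  # healthcare never exceeds societal
  for (st in c("A", "B", "C", "D", "E"))
    for (age in c(50, 70))
      expect_lte(state_cycle_cost(st, "ect", "main", age, "healthcare", p),
                 state_cycle_cost(st, "ect", "main", age, "societal", p) + 1e-9)
  # tunnel state under the indefinite-maintenance scenario uses the
  # months-2-to-5 cost
  expect_equal(
    state_cycle_cost("B6", "esk", "main", 50, "societal", p,
                     esk_indefinite = TRUE),
    state_cycle_cost("B3", "esk", "main", 50, "societal", p), tolerance = 1e-12)
  # states outside the configuration are rejected
  expect_error(state_cycle_cost("B6", "ect", "main", 50, "societal", p))
})

test_that("ECT session-frequency deltas follow the session fee and travel fare", {
  expect_equal(ect_frequency_delta(6, "societal"), -2 * (558 + 18.80))
  expect_equal(ect_frequency_delta(6, "societal"), -1153.60)
  expect_identical(ect_frequency_delta(8, "societal"), 0)
  expect_identical(ect_frequency_delta(8, "healthcare"), 0)
  expect_equal(ect_frequency_delta(12, "healthcare"), 4 * 558)
  expect_error(ect_frequency_delta(0, "societal"))
})

test_that("the direct/informal/travel split is consistent and guards against over-allocation", {
  split <- calibrate_direct_costs(base_params)
  expect_equal(split$direct + split$travel + split$informal,
               base_params$cost_table$total_ge65, tolerance = 1e-9)
  expect_true(all(split$informal >= -1e-9))
  expect_true(all(split$direct >= 0))
  # forcing more direct cost than the 65-plus total leaves a negative
  # informal residual
  p <- base_params
  p$cost_table$direct[p$cost_table$entry == "ect_acute"] <- 7000
  expect_error(calibrate_direct_costs(p), "negative informal-care residual")
  # the exported table carries both age bands and matches the components
  exp_tab <- export_cost_table(base_params)
  expect_identical(nrow(exp_tab), 2L * nrow(base_params$cost_table))
  old <- exp_tab[exp_tab$age_band == ">=65", ]
  expect_equal(old$societal,
               base_params$cost_table$total_ge65[
                 match(old$entry, base_params$cost_table$entry)],
               tolerance = 1e-9)
})

test_that("productivity scenarios touch only the societal perspective", {
  s_hc <- settings_for("ect", "main", "healthcare")
  base <- run_cohort(s_hc, base_params)
  doubled <- run_cohort(s_hc, base_params, scenario_mods(prod_mult = 2))
  halved <- run_cohort(s_hc, base_params, scenario_mods(prod_mult = 0.5))
  expect_identical(base$total_cost, doubled$total_cost)
  expect_identical(base$total_cost, halved$total_cost)
  expect_identical(base$total_qaly, doubled$total_qaly)
  s_soc <- settings_for("ect", "main", "societal")
  soc <- run_cohort(s_soc, base_params)
  soc2 <- run_cohort(s_soc, base_params, scenario_mods(prod_mult = 2))
  expect_gt(soc2$total_cost, soc$total_cost)
})
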