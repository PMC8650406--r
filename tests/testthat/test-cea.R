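test_that("dominance verdicts cover every quadrant of the CE plane", {
  inc <- function(dc, dq) incremental(fake_result(1000 + dc, 10 + dq),
                                      fake_result(1000, 10, arm = "esk"))
  # more QALYs, lower cost: ECT dominates
  expect_identical(inc(-500, 0.5)$verdict, "ect_dominates")
  expect_identical(inc(0, 0.5)$verdict, "ect_dominates")
  expect_identical(inc(-500, 0)$verdict, "ect_dominates")
  # fewer QALYs, higher cost: comparator dominates
  expect_identical(inc(500, -0.5)$verdict, "comparator_dominates")
  expect_identical(inc(500, 0)$verdict, "comparator_dominates")
  expect_identical(inc(0, -0.5)$verdict, "comparator_dominates")
  # trade-off quadrants yield an ICER
  ne <- inc(5000, 0.5)
  expect_identical(ne$verdict, "icer")
  expect_equal(ne$icer, 10000)
  sw <- inc(-5000, -0.5)
  expect_identical(sw$verdict, "icer")
  expect_equal(sw$icer, 10000)
  # identical arms: no dominance, ICER undefined
  tie <- inc(0, 0)
  expect_identical(tie$verdict, "icer")
  expect_true(is.na(tie$icer))
})

test_that("threshold classification follows net monetary benefit in every quadrant", {
  inc <- function(dc, dq) incremental(fake_result(1000 + dc, 10 + dq),
                                      fake_result(1000, 10, arm = "esk"))
  ne <- inc(12500, 0.5)  # ICER 25,000: between the NICE bounds
  expect_false(ne$cost_effective_low)
  expect_true(ne$cost_effective_high)
  # ECT cheaper but less effective at ICER 25,000: cost-effective only at
  # the lower threshold (savings outweigh the loss there)
  sw <- inc(-12500, -0.5)
  expect_true(sw$cost_effective_low)
  expect_false(sw$cost_effective_high)
  dom <- inc(-500, 0.5)
  expect_true(dom$cost_effective_low && dom$cost_effective_high)
})

test_that("mismatched runs are refused", {
  a <- run_cohort(settings_for("ect", "main", horizon_years = 2), base_params)
  b <- run_cohort(settings_for("esk", "main", horizon_years = 3), base_params)
  expect_error(incremental(a, b), "horizon_years")
  expect_error(incremental(a, a), "same arm")
  c_ <- run_cohort(settings_for("esk", "main", "healthcare",
                                horizon_years = 2), base_params)
  expect_error(incremental(a, c_), "perspective")
})

test_that("the scenario catalogue reproduces the published sensitivity design", {
  cat_m <- scenario_catalog("main")
  expect_length(cat_m, 22)
  expect_identical(cat_m[["6a"]]$mods$horizon_years, 5)
  expect_identical(cat_m[["6a"]]$perspective, "societal")
  expect_identical(cat_m[["4a"]]$mods$tp$tpA2B_ect, 0.5)
  expect_identical(cat_m[["3b"]]$mods$tp$tpA2B_esk, 0.5)
  expect_identical(cat_m[["5a"]]$mods$tp$tpC2B_ect, 0.9)
  expect_identical(cat_m[["5a"]]$mods$tp$tpC2B_esk, 0.9)
  expect_identical(cat_m[["9a"]]$mods$discount_rate, 0)
  expect_identical(cat_m[["1a"]]$mods$prod_mult, 2)
  expect_identical(cat_m[["2c"]]$mods$ect_sessions, 12)
  expect_true(cat_m[["8a"]]$mods$esk_indefinite)
  expect_identical(cat_m[["7a"]]$mods$u_ect_treatment, 0.3)
  expect_identical(cat_m[["7b"]]$mods$u_enhanced_remission, 0.85)
  # healthcare perspectives marked where the tables print them
  expect_identical(cat_m[["2b"]]$perspective, "healthcare")
  expect_identical(cat_m[["1b"]]$perspective, "societal")
  cat_mm <- scenario_catalog("maintenance")
  expect_true(all(vapply(cat_mm, `[[`, "", "variant") == "maintenance"))
  expect_error(scenario_mods(tp = list(nonsense = 1)), "unknown transition")
})

test_that("short-horizon scenario runs reproduce manual incremental analysis", {
  # 5-year horizon keeps this quick while exercising the full path
  entry <- scenario_catalog("main")[["6a"]]
  ce <- run_scenario(entry, base_params)
  ect <- run_cohort(settings_for("ect", "main", horizon_years = 5),
                    base_params)
  esk <- run_cohort(settings_for("esk", "main", horizon_years = 5),
                    base_params)
  manual <- incremental(ect, esk)
  expect_equal(ce$delta_cost, manual$delta_cost, tolerance = 1e-12)
  expect_equal(ce$delta_qaly, manual$delta_qaly, tolerance = 1e-12)
  expect_identical(ce$verdict, manual$verdict)
  # ECT costs less and yields more QALYs over five years (dominance), the
  # headline pattern of the main model
  expect_identical(ce$verdict, "ect_dominates")
})

test_that("scenario 7 reassigns utilities to the intended states only", {
  mods <- scenario_mods(u_ect_treatment = 0.3, u_enhanced_remission = 0.85)
  s <- settings_for("ect", "main", horizon_years = 3)
  base <- run_cohort(s, base_params)
  mod <- run_cohort(s, base_params, mods)
  # costs untouched, QALYs move
  expect_identical(base$total_cost, mod$total_cost)
  expect_false(identical(base$total_qaly, mod$total_qaly))
  # esketamine arm: no ECT-treatment disutility, remission states upgraded
  sk <- settings_for("esk", "main", horizon_years = 3)
  base_k <- run_cohort(sk, base_params)
  mod_k <- run_cohort(sk, base_params, mods)
  expect_gt(mod_k$total_qaly, base_k$total_qaly)
})
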