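# shared fixtures: all built in code, no stored data

base_params <- trd_parameters()

settings_for <- function(arm = "ect", variant = "main",
                         perspective = "societal", ...) {
  model_settings(arm = arm, variant = variant, perspective = perspective, ...)
}

# a degenerate bundle where remission is certain on treatment and nobody
# relapses or dies: closed-form QALY accounting becomes exact
certain_remission_params <- function() {
  p <- trd_parameters()
  p$transitions$tpA2B_ect <- 1
  p$transitions$tpB2C_ect <- 0
  p$transitions$tpDep2G <- 0
  p$transitions$remission_mortality[] <- 0
  p
}

# random valid parameter bundle for property tests (probabilities jittered
# on the logit-ish scale, invariants preserved)
random_params <- function() {
  p <- trd_parameters()
  jit <- function(x, lo = 0, hi = 0.95) pmin(hi, pmax(lo, x * runif(1, 0.3, 1.8)))
  tr <- p$transitions
  for (nm in c("tpA2B_ect", "tpA2B_esk", "tpB2C_ect", "tpB2C_mect",
               "tpB2C_esk", "tpD2E", "tpE2D"))
    tr[[nm]] <- jit(tr[[nm]])
  tr$tpDep2G <- jit(tr$tpDep2G, hi = 0.04)
  tr$remission_mortality <- cumsum(runif(7, 0, 5e-4))
  names(tr$remission_mortality) <- names(p$transitions$remission_mortality)
  p$transitions <- tr
  stopifnot(length(validate_parameters(p)) == 0)
  p
}

random_settings <- function() {
  model_settings(arm = sample(c("ect", "esk"), 1),
                 variant = sample(c("main", "maintenance"), 1),
                 perspective = sample(c("societal", "healthcare"), 1),
                 horizon_years = sample(c(5, 10, 35), 1),
                 discount_rate = runif(1, 0, 0.06))
}

# minimal arm-result stand-in for dominance-logic tests
fake_result <- function(cost, qaly, arm = "ect") {
  structure(list(total_cost = cost, total_qaly = qaly,
                 settings = model_settings(arm = arm)),
            class = "trd_arm_result")
}
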