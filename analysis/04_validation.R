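#!/usr/bin/env Rscript
# Model validation: microsimulation oracle versus the cohort recursion, and
# parameter recovery from synthetic trials.

suppressPackageStartupMessages(library(trdcea))
dir.create("results", showWarnings = FALSE)

params <- trd_parameters()

## 1. Individual-level microsimulation vs cohort recursion --------------------
cat("Microsimulation oracle (n = 100,000) vs cohort totals:\n")
rows <- list()
for (cfg in list(c("ect", "main"), c("esk", "main"), c("ect", "maintenance"))) {
  s <- model_settings(arm = cfg[1], variant = cfg[2])
  coh <- run_cohort(s, params)
  ms <- microsimulate(s, params, n = 1e5, seed = 7)
  rows[[paste(cfg, collapse = "-")]] <- data.frame(
    arm = cfg[1], variant = cfg[2],
    cohort_cost = coh$total_cost, microsim_cost = ms$mean_cost,
    cost_z = (ms$mean_cost - coh$total_cost) / ms$se_cost,
    cohort_qaly = coh$total_qaly, microsim_qaly = ms$mean_qaly,
    qaly_z = (ms$mean_qaly - coh$total_qaly) / ms$se_qaly)
}
val <- do.call(rbind, c(rows, make.row.names = FALSE))
write.csv(val, "results/validation_microsim.csv", row.names = FALSE)
print(val, digits = 4, row.names = FALSE)
cat("All |z| values should sit well inside +-3 Monte-Carlo SE.\n\n")

## 2. Parameter recovery from synthetic trials --------------------------------
cat("Recovery of derivable inputs from synthetic trials (n = 100,000):\n")
ev <- evidence_summaries()
trials <- lapply(seq_len(nrow(ev)), function(i)
  simulate_trial(1e5, ev$P[i], ev$window_days[i], seed = 100 + i,
                 rr = ev$rr[i]))
names(trials) <- ev$param
est <- recover_parameters(trials)
rec <- data.frame(param = ev$param,
                  truth = unlist(params$transitions[ev$param]),
                  estimate = est,
                  rel_err = est / unlist(params$transitions[ev$param]) - 1)
write.csv(rec, "results/validation_recovery.csv", row.names = FALSE)
print(rec, digits = 4, row.names = FALSE)
cat("\nEstimates converge on the printed per-cycle inputs; sampling error\n")
cat("at the source-trial sizes is explored in the test suite's coverage\n")
cat("experiment (binomial 95% intervals, nominal coverage).\n")
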