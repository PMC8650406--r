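#!/usr/bin/env Rscript
# Derive the per-cycle transition probabilities from their source-trial
# summaries and check them against the model's printed inputs.
#
# Five of the model inputs are derivable from published event proportions
# over stated follow-up windows via the constant-hazard conversion
# (r = -ln(1-P)/t, p = 1 - exp(-rt)); the rest (remission on ECT and on
# esketamine, relapse on standard treatment, lifetable mortality) enter as
# printed per-cycle values.

suppressPackageStartupMessages(library(trdcea))
dir.create("results", showWarnings = FALSE)

params <- trd_parameters()
ev <- evidence_summaries()
ev$derived_per_cycle <- mapply(mortality_with_relative_risk,
                               ev$P, ev$window_days, ev$rr,
                               MoreArgs = list(t_target = 30))
ev$model_input <- unlist(params$transitions[ev$param])
ev$agree_3sf <- signif(ev$derived_per_cycle, 3) == signif(ev$model_input, 3)

write.csv(ev, "results/transition_inputs.csv", row.names = FALSE)
cat("Per-cycle transition probabilities derived from source summaries:\n")
print(ev, digits = 4)
cat("\nAll derivable inputs agree with the model inputs at 3 s.f.:",
    all(ev$agree_3sf), "\n")
cat("Note: relapse on standard treatment (0.232/cycle) is not derivable\n",
    "from its source summary (64.6% over 3.1 months gives ~0.28 under any\n",
    "day-count convention); the printed per-cycle value is used as-is.\n")
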