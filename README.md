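# trdcea

A Markov cohort cost-utility model comparing **electroconvulsive therapy
(ECT)** — with or without maintenance ECT — against **intranasal
esketamine** for adults with treatment-resistant depression (TRD), written
for health economists and psychiatry researchers who want the published
UK analysis as tested, configurable, fully inspectable code rather than a
spreadsheet.

## The model

A cohort enters at age 45, fully depressed, and is followed in 30-day
cycles for 35 years from a societal or healthcare perspective. Health
states cover depression on index treatment (A), remission after it (B,
expanded into monthly tunnel states where costs depend on time since
remitting), re-treatment after relapse (C), depression and remission on
standard antidepressant care (D, E), post-esketamine remission (F) and
death (G). Per-cycle transition probabilities are derived from trial
summaries through the constant-hazard conversion

    r = -ln(1 - P) / t,      p = 1 - exp(-r t')

(e.g. 50% relapse over six months → 0.108 per 30-day cycle). Costs (2019
GBP) combine direct healthcare, human-capital productivity loss at the
general wage (zero from retirement at 65), informal care and travel;
utilities are 0.81/0.57 QALY-years for remission/depression; both streams
are discounted at 3.5%/year. Strategies are compared by the incremental
cost-effectiveness ratio ICER = ΔC/ΔQALY, with dominance and the NICE
£20,000–£30,000/QALY range for classification, plus the published
deterministic sensitivity scenarios (1a–9b).

## Worked example

```r
library(trdcea)
params <- trd_parameters()          # full printed input set, validated

# derive a per-cycle input from its source summary
signif(rescale_prob(0.50, 182.5, 30), 3)
#> [1] 0.108

# base case, main model, societal perspective
s_ect <- model_settings(arm = "ect", variant = "main", perspective = "societal")
s_esk <- model_settings(arm = "esk", variant = "main", perspective = "societal")
ce <- incremental(run_cohort(s_ect, params), run_cohort(s_esk, params))
ce
#> <trd_ce_result>
#>   ECT: 321,764 GBP / 9.89 QALY; comparator: 327,899 GBP / 9.46 QALY
#>   incremental: -6,135 GBP / 0.43 QALY -> ect_dominates
```

ECT yields more QALYs at lower cost, so it *dominates* esketamine and no
ICER is defined — the headline result. With maintenance ECT the extra
sessions buy more remission time at a price:

```r
mm <- incremental(
  run_cohort(model_settings(arm = "ect", variant = "maintenance"), params),
  run_cohort(model_settings(arm = "esk", variant = "maintenance"), params))
mm
#> <trd_ce_result>
#>   ECT: 370,952 GBP / 10.96 QALY; comparator: 327,899 GBP / 9.46 QALY
#>   incremental: 43,053 GBP / 1.50 QALY -> ICER 28,626 GBP/QALY
```

£28,626 per QALY gained sits inside the NICE range: cost-effective at the
£30,000 bound, not at £20,000. `run_table("main")` regenerates the full
base-case + sensitivity table; `scenario_catalog()` lists every scenario;
`microsimulate()` provides an individual-level Monte-Carlo oracle for the
cohort recursion; `simulate_trial()`/`recover_parameters()` test the
input-derivation chain on synthetic trials. Note that the discounted
lifetime totals differ from the published tabulations, whose 35-year
discounting is internally inconsistent — the package applies compound
discounting correctly and reproduces the published undiscounted and
5-year rows closely; see the methods vignette
(`vignettes/trd-cost-utility.Rmd`) for the analysis.

## The analysis workflow

Numbered drivers under `analysis/` rebuild every result table into
`results/`:

```sh
Rscript analysis/01_transition_inputs.R   # derive + verify per-cycle inputs
Rscript analysis/02_base_case.R           # base-case totals, ICERs, traces
Rscript analysis/03_sensitivity.R         # full scenario tables, both models
Rscript analysis/04_validation.R          # microsim oracle + parameter recovery
```

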