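# her2cea

Cost-effectiveness analysis of one-year adjuvant trastuzumab for HER2-positive
early-stage breast cancer in the Vietnamese setting, from a societal
perspective.

Trastuzumab is highly effective adjuvant therapy for HER2+ early breast
cancer, but at roughly 790 million VND (≈35,000 US$) per one-year course it is
among the costliest items in the national insurance benefit package. This
package is for health-economics analysts and HTA practitioners who need a
tested, reproducible implementation of the full evaluation: a Markov cohort
state-transition model comparing trastuzumab + chemotherapy against
chemotherapy (paclitaxel) alone, with deterministic base case, probabilistic
and one-way sensitivity analysis, acceptability curves, value-of-information,
threshold pricing, and a weight-based vial-packing drug-cost calculator.

## The model

A closed cohort of women enters disease-free at age 50 and moves annually
among six states — disease-free (DFS), DFS after congestive heart failure
(trastuzumab cardiotoxicity), local-regional recurrence, DFS after recurrence,
metastatic, dead — over a lifetime horizon. Key mechanics:

* treatment effect as hazard ratios (recurrence 0.58, metastasis 0.48)
  applied for five years via the rate-based conversion
  `p' = 1 − (1 − p)^HR`;
* cardiotoxicity only in the first year (0.198 vs 0.007), with lifelong
  utility decrement and trastuzumab discontinuation;
* no new recurrences after model year 20; cancer death only from the
  metastatic state (0.295/year); background mortality from an age-indexed
  life table competes in every state;
* costs (2020 VND) and effects discounted at 3%/year; ICERs judged against
  willingness-to-pay thresholds of 83 and 249 million VND/QALY (1× and 3×
  GDP per capita).

Results are reported per person and scaled to the eligible national cohort
(5,052 women/year). Because the national female life table is not bundled,
the package generates and ships a clearly-labelled Gompertz–Makeham
approximation (`vietnam_2020_approx.tsv`); absolute results below depend on
it, the qualitative conclusions do not (see the methods vignette).

## Worked example

```r
library(her2cea)

params <- load_config(system.file("extdata", "basecase.yaml", package = "her2cea"))
lt     <- read_life_table(system.file("extdata", "vietnam_2020_approx.tsv", package = "her2cea"))

bc <- run_base_case(params, lt)
bc$icer
#> Incremental: cost 806650680 VND (35465 US$), 1.1558 LY, 0.7487 QALY [trade-off]
#> ICER: 1077455795 VND (47371 US$) per QALY; 697939583 VND (30685 US$) per LY

psa <- run_psa_model(params, lt, n = 2000, seed = 42)
ceac(psa, lambdas = c(83e6, 249e6))
#>     lambda p_trastuzumab p_chemo
#> 1 8.30e+07             0       1
#> 2 2.49e+08             0       1

th <- threshold_price(249e6, params, lt)
sprintf("440mg vial threshold price at 3x GDP: %.0f VND (%.0f%% reduction)",
        th$price_440, 100 * (1 - th$scale))
#> "440mg vial threshold price at 3x GDP: 9679296 VND (79% reduction)"
```

Reading: adding one year of trastuzumab costs an extra ~807 million VND per
person for ~0.75 extra QALYs — an ICER of ~1,077 million VND/QALY, far above
both thresholds, and not a single probabilistic draw is cost-effective at
either one (hence the acceptability probabilities of 0 and an EVPI of 0: the
decision is certain at current prices). The drug price would have to fall to
~9.7 million VND per 440 mg vial (a 79% reduction on this life table) before
the therapy becomes cost-effective at 3× GDP per capita. Vial sharing
(`sharing = TRUE`) lowers the ICER but not below the threshold.

A command-line interface wraps the same functions:

```sh
exec/her2cea run --config inst/extdata/basecase.yaml \
  --lifetable inst/extdata/vietnam_2020_approx.tsv --out results/
exec/her2cea psa --config ... --lifetable ... --seed 7 --iterations 10000 --out results/
```

Subcommands: `run`, `psa`, `tornado`, `threshold`, `scenario`, `evpi`,
`drugcost`, `simulate-data`; every run writes tab-delimited tables plus a
`manifest.json`, and identical seeds give byte-identical outputs.

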