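---
title: "Model and methods: cost-effectiveness of one-year adjuvant trastuzumab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: cost-effectiveness of one-year adjuvant trastuzumab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(her2cea)
```

## The decision problem

`her2cea` evaluates whether adding one year of adjuvant trastuzumab to
chemotherapy (paclitaxel) is value for money for HER2-positive early-stage
breast cancer in the Vietnamese setting, from a societal perspective. The
comparison is a Markov cohort state-transition model: a closed cohort of
women, entering disease-free at age 50, moves annually among six health
states, and each arm accumulates lifetime discounted costs (2020 VND), life
years (LY) and quality-adjusted life years (QALY). The decision metric is the
incremental cost-effectiveness ratio (ICER)
$\Delta C / \Delta E$ against willingness-to-pay thresholds of one and three
times GDP per capita (83 and 249 million VND per QALY).

## Model structure

States, in the fixed order used by every matrix and trace
(`health_states()`):

1. **DFS** — disease-free after primary treatment;
2. **DFS_CHF** — disease-free after a congestive-heart-failure event
   (trastuzumab cardiotoxicity; treatment is discontinued);
3. **LRR** — local-regional recurrence;
4. **DFS_POST_LRR** — disease-free again after treated local-regional
   recurrence;
5. **MET** — metastatic disease;
6. **DEAD** — absorbing.

Structural assumptions:

* the treatment effect (hazard ratios on recurrence and metastasis) lasts
  five years (`benefit_duration`);
* cardiotoxicity can occur only in the first model year, in both arms
  (trastuzumab 0.198, chemotherapy 0.007), and carries no excess mortality —
  its burden enters through the lower utility (0.670) and an annual
  management cost;
* no new recurrences arise beyond model year 20 (`recurrence_cutoff`), though
  established disease keeps progressing;
* cancer death occurs only from the metastatic state (annual probability
  0.295); every alive state is additionally exposed to background mortality
  from the life table;
* after a local-regional recurrence, the metastasis hazard is multiplied by
  3.64, applied in both the recurrence state and the post-recurrence
  disease-free state;
* after CHF, recurrence risks revert to the untreated baselines
  (configurable via `p_lrr_chf` / `p_met_chf`, which default to the
  baselines; they are varied as distinct parameters in the sensitivity
  analyses).

The hazard-ratio-on-DFS value (0.760) is carried in the parameter set for
completeness but does not enter the transition structure, which is driven by
the recurrence-specific (0.580) and metastasis-specific (0.480) ratios; it is
therefore excluded from the PSA and tornado.

## Transition probabilities

Hazard ratios convert to annual probabilities by the rate-based survival
identity

$$p' = 1 - (1 - p)^{\mathrm{HR}},$$

which stays in $[0,1)$ for any positive HR — the 3.64 post-recurrence
multiplier gives 0.257 rather than the out-of-scale 0.286 a linear
$p \times \mathrm{HR}$ would produce. The linear rule is available behind
`settings$hr_method = "linear"` for sensitivity to this convention.

Within a cycle, background death competes first: with $q$ the life-table
annual death probability at the attained age, every disease-event probability
is scaled by $(1-q)$ and $q$ flows to DEAD, so rows are stochastic by
construction (checked to $10^{-12}$ in the tests). A configuration whose raw
event probabilities sum above one fails loudly, naming the state and cycle.

## Rewards, discounting, horizon

Rewards accrue on start-of-cycle occupancy: each cycle $t$ contributes
occupancy-weighted LYs, utilities and annual state costs, discounted by
$(1+r)^{-t}$ with $r = 0.03$ for both costs and effects. The arm-specific
one-year therapy cost is a one-off added at $t = 0$ undiscounted. The
simulation runs from the start age to `max_age` (100, the last life-table
row) or until the alive fraction falls below $10^{-12}$. A half-cycle
correction flag (`half_cycle_correction`) averages start- and end-of-cycle
occupancy instead; it is off by default, matching the conventional
annual-cycle spreadsheet layout, and the toy-model closed forms in the test
suite pin the default convention to $10^{-9}$.

Two independent checks anchor the engine: `make_toy_model()` builds
single-live-state configurations whose discounted totals have the geometric
closed form $\sum_t ((1-p)/(1+r))^t$, and `microsim()` re-simulates the same
matrices at the individual level — the cohort engine must sit within three
Monte-Carlo standard errors of it (run at $n = 200{,}000$ in the acceptance
suite). That oracle caught a real defect during development (individuals
being transitioned twice in one cycle), which is exactly the class of error a
trace-conservation test alone does not see.

## Costs

The one-year trastuzumab therapy cost is the sum of the drug aggregate, HER2
detection, other direct medical costs and direct non-medical costs
(820,835,916 VND at the bundled values), plus the drug-only paclitaxel cost
of the concurrent chemotherapy; the comparator arm carries the full
paclitaxel treatment cost (32,116,418 VND). The drug-only paclitaxel figure
is not separately available, so `paclitaxel_drug_only` defaults to the full
treatment cost and cancels in the increment; users with a better estimate can
set it in the configuration.

Two drug-cost modes exist because the bundled aggregate (787,384,650 VND
base; 570,022,437 VND with vial sharing) reflects micro-costing (weight
distributions, wastage and reimbursement detail) that cannot be rebuilt from
list vial prices alone: `drug_cost_mode = "printed"` (default) uses the
aggregates directly, while `"computed"` derives them from the vial-packing
calculator — per administration (8 mg/kg loading, then 6 mg/kg every 3 weeks,
18 administrations/year), the cheapest integer combination of 440 mg and
150 mg vials covering the dose, summed over the course. At the 52.9 kg
reference weight the calculator gives 820,741,950 VND without sharing and
603,017,349 VND with ideal sharing (total milligrams at the best per-mg
price), bracketing the bundled aggregates; the calculator is exposed both as
functions and via the `drugcost` CLI subcommand.

## Uncertainty analysis

**PSA.** 10,000 joint draws by default: beta for transition probabilities
and utilities, log-normal for the relative treatment effects (the two
active hazard ratios and the post-recurrence multiplier), gamma for costs.
Parameters without a published 95% CI use ±10% of the base value, read as a
95% interval, so SD = (hi − lo)/3.92; method-of-moments fits then reproduce
the base value as the distribution mean (median for log-normal) to $10^{-9}$
relative. Draws are mutually independent — no correlation structure is
imposed, including across the three relative effects, since no joint
estimates are available. Both arms are run on the *same* draw, so
between-arm differences reflect only the model structure.

**CEAC.** At each willingness-to-pay value the probability that the
trastuzumab strategy is cost-effective is the fraction of draws with positive
incremental net monetary benefit ($\lambda\,\Delta QALY - \Delta C$); ties go
to the comparator. Default grid: 0 to 1,000 million VND/QALY in 5-million
steps.

**EVPI.** Per person,
$E[\max(0, \mathrm{iNMB})] - \max(0, E[\mathrm{iNMB}])$; population EVPI
scales by one annual treatment cohort (5,052), with no discounting over
future cohorts (no decision-lifetime convention is imposed).

**Tornado.** One-way ICER recomputation at each parameter's range ends
(published CIs where configured, otherwise ±10%), sorted by span; a range end
that breaks the model is flagged rather than fatal.

**Threshold price.** Bisection on a common multiplicative factor applied to
both vial prices (and hence the drug aggregate, which is proportional to
them) until the ICER matches the target threshold to 0.01%. Scaling both
vials by one factor preserves the current 440:150 price ratio (≈2.93:1); a
closed-form check against the affine cost structure to $10^{-6}$ relative is
part of the test suite.

## Synthetic inputs

The national 2020 female life table is not redistributable here, so the
package generates and ships a clearly-labelled approximation
(`vietnam_2020_approx.tsv`): a Gompertz–Makeham law
$h(x) = a + c\,e^{bx}$ with $a = 5\times10^{-4}$, $b = 0.11$,
$c = 8\times10^{-6}$ over ages 0–100 ($q_{100}$ forced to 1), chosen once to
give a remaining female life expectancy at age 50 of about 31 years. It
reproduces the *shape* of adult female mortality but not childhood mortality,
period shocks, or the exact national schedule — so model outputs that hinge
on absolute background mortality (total LYs, hence the ICER level) differ
from what the national table would give, while structural properties,
orderings and the qualitative conclusion do not. On this table the
deterministic ICER is about 1,077 million VND/QALY (test and acceptance
output), well above both thresholds; all PSA draws stay in the north-east
quadrant and the probability of cost-effectiveness at 83 and 249 million
VND/QALY is 0%, so the study conclusion — not cost-effective at current
prices — is insensitive to the table approximation, and EVPI is 0 at both
thresholds. `jitter_params()` provides multiplicative perturbations for
robustness testing.

## Numerical conventions and problem sizes

* Alive-fraction stopping tolerance $10^{-12}$; occupancy conservation
  asserted to $10^{-9}$ per cycle.
* VND amounts are carried as exact doubles (integral below $2^{53}$) and
  reported as integers; US$ figures are rounded to whole dollars at 22,745
  VND/US$ for reporting, with unrounded values available.
* CEAC ties favour the comparator; ICERs are reported only in trade-off
  quadrants, with dominance flagged otherwise and a zero-QALY increment
  flagged undefined rather than an error.
* All randomness (PSA, microsimulation, jittering) flows from explicit seeds;
  identical seeds give byte-identical output tables.
* Test-suite problem sizes: microsimulation oracle at 200,000 individuals,
  PSA at 10,000 iterations in the acceptance checks and 20–60 draws in unit
  tests — sizes chosen so the full suite exercises every analysis end to end
  at the default study scale.

## Limitations

* Costs and utilities enter as aggregate constants; no micro-costing or
  EQ-5D scoring is re-performed, and payer/insurance splits are out of scope
  (societal totals only).
* The bundled life table is an approximation; users with the national table
  should pass it via `read_life_table()` — every analysis accepts any
  conforming table.
* Transition probabilities are time-homogeneous within the benefit/cutoff
  regimes; no tunnel states or individual heterogeneity beyond the
  microsimulation oracle.
* Indirect/productivity costs are excluded.
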