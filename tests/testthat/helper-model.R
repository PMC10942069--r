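# Shared fixtures: the base-case parameter set, the synthetic life table, and
# a flat life table with constant annual death probability.

base_params <- function() default_params()

base_lifetable <- function() vietnam_lifetable_approx()

flat_lifetable <- function(q, ages = 0:120) {
  life_table(ages, c(rep(q, length(ages) - 1), 1))
}

# A parameter set in which the two arms are structurally identical: null
# treatment effect, equal first-year cardiotoxicity, equal year-one costs.
null_effect_params <- function() {
  p <- default_params()
  p$clinical$hr_lrr <- 1
  p$clinical$hr_met <- 1
  p$clinical$hr_dfs <- 1
  p$clinical$p_chf_trast <- p$clinical$p_chf_chemo
  p$costs$trast_drug <- 0
  p$costs$trast_drug_sharing <- 0
  p$costs$her2_detection <- 0
  p$costs$trast_other_direct_medical <- 0
  p$costs$trast_direct_nonmedical <- 0
  p$costs$paclitaxel_drug_only <- p$costs$paclitaxel_treatment
  p
}

# Minimal arm_result stand-in for testing icer() arithmetic in isolation.
fake_arm <- function(cost, ly, qaly) {
  structure(list(per_person = list(cost = cost, ly = ly, qaly = qaly)),
            class = "arm_result")
}
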