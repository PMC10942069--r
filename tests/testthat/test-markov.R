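test_that("hazard-ratio conversion follows the rate-based survival identity", {
  expect_equal(hr_adjust(0.0785, 1), 0.0785)
  expect_equal(hr_adjust(0, 0.48), 0)
  expect_equal(hr_adjust(0.0785, 0.48), 1 - (1 - 0.0785)^0.48, tolerance = 1e-15)
  expect_equal(hr_adjust(1, 2), 1)
  # the multiplier after recurrence stays a valid probability under the
  # rate-based transform even though linear application would not overflow
  expect_equal(hr_adjust(0.0785, 3.64), 1 - (0.9215)^3.64)
  expect_equal(hr_adjust(0.0785, 3.64, method = "linear"), 0.0785 * 3.64)
  expect_error(hr_adjust(-0.1, 1), "\\[0, 1\\]")
  expect_error(hr_adjust(0.5, 0), "positive")
})

test_that("transition matrices implement the stated arm/cycle structure", {
  p <- base_params()
  lt <- flat_lifetable(0.003)
  p$settings$start_age <- 0
  p$settings$max_age <- 60

  # chemotherapy arm, cycle 3: baseline recurrence risks scaled by survival
  M <- build_matrix("chemo", cycle = 3, age = 3, p, lt)
  expect_equal(M["DFS", "LRR"], 0.0294 * 0.997)
  expect_equal(M["DFS", "MET"], 0.0785 * 0.997)
  expect_equal(M["DFS", "DEAD"], 0.003)
  expect_equal(M["DFS", "DFS_CHF"], 0)
  expect_equal(M["DFS", "DFS"], 1 - sum(M["DFS", -1]))

  # cardiotoxicity only at cycle 0, by arm
  M0t <- build_matrix("trastuzumab", 0, 0, p, lt)
  M0c <- build_matrix("chemo", 0, 0, p, lt)
  expect_equal(M0t["DFS", "DFS_CHF"], 0.198 * 0.997)
  expect_equal(M0c["DFS", "DFS_CHF"], 0.007 * 0.997)
  expect_equal(build_matrix("trastuzumab", 1, 1, p, lt)["DFS", "DFS_CHF"], 0)

  # treatment benefit in the first five cycles only
  M4 <- build_matrix("trastuzumab", 4, 4, p, lt)
  M5 <- build_matrix("trastuzumab", 5, 5, p, lt)
  expect_equal(M4["DFS", "MET"], hr_adjust(0.0785, 0.48) * 0.997)
  expect_equal(M5["DFS", "MET"], 0.0785 * 0.997)

  # no new recurrences from cycle 20 onward, from DFS and DFS_CHF alike
  M25 <- build_matrix("trastuzumab", 25, 25, p, lt)
  expect_equal(M25["DFS", "LRR"], 0)
  expect_equal(M25["DFS", "MET"], 0)
  expect_equal(M25["DFS_CHF", "MET"], 0)
  # but established disease keeps progressing
  expect_gt(M25["LRR", "MET"], 0)
  expect_gt(M25["MET", "DEAD"], 0)

  # after CHF the recurrence risks are the untreated baselines in both arms
  expect_equal(M4["DFS_CHF", "MET"], 0.0785 * 0.997)
  expect_equal(M4["DFS_CHF", "LRR"], 0.0294 * 0.997)

  # metastatic mortality: independent competing causes
  expect_equal(M4["MET", "DEAD"], 1 - (1 - 0.295) * 0.997)

  # null treatment effect makes the arms identical except first-cycle CHF
  pn <- null_effect_params()
  pn$clinical$p_chf_trast <- 0.198; pn$clinical$p_chf_chemo <- 0.007
  pn$settings$start_age <- 0; pn$settings$max_age <- 60
  for (cy in c(1, 3, 7, 21)) {
    expect_equal(build_matrix("trastuzumab", cy, cy, pn, lt),
                 build_matrix("chemo", cy, cy, pn, lt))
  }
})

test_that("every generated matrix is row-stochastic at every cycle", {
  lt <- base_lifetable()
  for (seed in 1:5) {
    p <- jitter_params(base_params(), 0.1, seed = seed)
    for (arm in c("trastuzumab", "chemo")) {
      for (cy in 0:49) {
        M <- build_matrix(arm, cy, 50 + cy, p, lt)
        expect_true(all(M >= 0 & M <= 1))
        expect_lt(max(abs(rowSums(M) - 1)), 1e-12)
        expect_equal(M["DEAD", ], c(DFS = 0, DFS_CHF = 0, LRR = 0,
                                    DFS_POST_LRR = 0, MET = 0, DEAD = 1))
      }
    }
  }
  # event probabilities exceeding 1 are rejected with state and cycle named
  pbad <- base_params()
  pbad$clinical$p_lrr_base <- 0.6
  pbad$clinical$p_met_base <- 0.6
  expect_error(build_matrix("chemo", 3, 53, pbad, lt), "DFS at cycle 3")
})

test_that("cohort traces conserve occupancy and mortality is monotone", {
  p <- base_params(); lt <- base_lifetable()
  for (arm in c("trastuzumab", "chemo")) {
    res <- run_cohort(arm, p, lt)
    occ <- as.matrix(res$trace[, health_states()])
    expect_lt(max(abs(rowSums(occ) - 1)), 1e-9)
    alive <- 1 - occ[, "DEAD"]
    expect_true(all(diff(alive) <= 1e-12))
    pp <- res$per_person
    expect_lte(pp$cost, pp$cost_undisc)
    expect_lte(pp$ly, pp$ly_undisc)
    expect_lte(pp$qaly + 1e-12, pp$ly)
    expect_equal(res$cohort$qaly, pp$qaly * p$settings$cohort_size)
  }
})

test_that("cohort engine matches the closed-form toy model to 1e-9", {
  for (case in list(list(p = 0, u = 1, cost = 0, r = 0, horizon = 3),
                    list(p = 0.5, u = 1, cost = 0, r = 0, horizon = 60),
                    list(p = 0.5, u = 0.7, cost = 1e6, r = 0.03, horizon = 60),
                    list(p = 0.1, u = 0.832, cost = 1400846, r = 0.03, horizon = 80))) {
    toy <- do.call(make_toy_model, case)
    res <- run_cohort("chemo", toy$params, toy$lifetable)
    expect_equal(res$per_person$ly, toy$expected$ly, tolerance = 1e-9)
    expect_equal(res$per_person$qaly, toy$expected$qaly, tolerance = 1e-9)
    expect_equal(res$per_person$cost - toy$params$costs$paclitaxel_treatment,
                 toy$expected$cost, tolerance = 1e-9)
  }
  # p = 0, r = 0, horizon T: perfect survival accrues exactly T life years
  toy <- make_toy_model(p = 0, u = 1, cost = 0, r = 0, horizon = 3)
  res <- run_cohort("chemo", toy$params, toy$lifetable)
  expect_equal(res$per_person$ly, 3)
  expect_equal(res$per_person$qaly, 3)
  # geometric limit: p = 0.5, r = 0 gives QALY -> 2 over a long horizon
  toy <- make_toy_model(p = 0.5, u = 1, r = 0, horizon = 60)
  expect_equal(run_cohort("chemo", toy$params, toy$lifetable)$per_person$qaly,
               2, tolerance = 1e-9)
})

test_that("certain immediate death accrues exactly one start-of-cycle reward", {
  p <- base_params()
  lt <- flat_lifetable(1, ages = 0:120)
  res <- run_cohort("chemo", p, lt)
  expect_equal(res$per_person$ly, 1)
  expect_equal(res$per_person$qaly, p$utilities$u_dfs)
})

test_that("null treatment effect yields exactly zero increments", {
  p <- null_effect_params(); lt <- base_lifetable()
  bc <- run_base_case(p, lt)
  expect_identical(bc$icer$d_cost, 0)
  expect_identical(bc$icer$d_qaly, 0)
  expect_identical(bc$icer$d_ly, 0)
})

test_that("a stronger metastasis effect never lowers the treated arm's life years", {
  p <- base_params(); lt <- base_lifetable()
  lys <- vapply(c(1, 0.8, 0.48, 0.2), function(hr) {
    p$clinical$hr_met <- hr
    run_cohort("trastuzumab", p, lt)$per_person$ly
  }, numeric(1))
  expect_true(all(diff(lys) >= 0))
})

test_that("microsimulation oracle agrees with the cohort engine", {
  # degenerate model: exact agreement
  toy <- make_toy_model(p = 0, u = 0.8, cost = 5, r = 0.03, horizon = 10)
  co <- run_cohort("chemo", toy$params, toy$lifetable)
  ms <- microsim("chemo", toy$params, toy$lifetable, n_individuals = 50, seed = 1)
  expect_equal(ms$mean$ly, co$per_person$ly, tolerance = 1e-12)
  expect_equal(ms$mean$qaly, co$per_person$qaly, tolerance = 1e-12)
  expect_equal(ms$mean$cost, co$per_person$cost, tolerance = 1e-12)

  # determinism under seed
  p <- base_params(); lt <- base_lifetable()
  m1 <- microsim("trastuzumab", p, lt, 500, seed = 11)
  m2 <- microsim("trastuzumab", p, lt, 500, seed = 11)
  expect_identical(m1, m2)

  # stochastic agreement within 3 Monte-Carlo standard errors
  co <- run_cohort("trastuzumab", p, lt)
  ms <- microsim("trastuzumab", p, lt, 20000, seed = 2)
  for (k in c("cost", "ly", "qaly")) {
    expect_lt(abs(ms$mean[[k]] - co$per_person[[k]]), 3 * ms$se[[k]])
  }
})
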