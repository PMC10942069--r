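test_that("ICER arithmetic and dominance classification", {
  p <- default_params()
  ic <- icer(fake_arm(200, 4, 4), fake_arm(100, 2, 2), p)
  expect_equal(ic$icer_qaly, 50)
  expect_equal(ic$icer_ly, 50)
  expect_equal(ic$dominance, "trade-off")

  ic <- icer(fake_arm(90, 2.5, 2.5), fake_arm(100, 2, 2), p)
  expect_equal(ic$dominance, "dominant")
  expect_true(is.na(ic$icer_qaly))

  ic <- icer(fake_arm(110, 1.5, 1.5), fake_arm(100, 2, 2), p)
  expect_equal(ic$dominance, "dominated")

  ic <- icer(fake_arm(110, 2, 2), fake_arm(100, 2, 2), p)
  expect_true(ic$undefined)
  expect_true(is.na(ic$icer_qaly))

  # division cross-check at the published increment scale
  ic <- icer(fake_arm(888453971, 3.0914, 1.71), fake_arm(0, 0, 0), p)
  expect_equal(ic$icer_ly, 888453971 / 3.0914)
  expect_lt(abs(ic$icer_ly - 287390000), 5e5)
})

test_that("net monetary benefit and its threshold identity", {
  expect_equal(nmb(100, 2, 0), -100)
  expect_equal(nmb(100, 2, 50), 0)
  set.seed(33)
  d_cost <- runif(50, 1e6, 1e9); d_qaly <- runif(50, 0.1, 3)
  for (l in c(83e6, 249e6, 519616972)) {
    expect_identical(nmb(d_cost, d_qaly, l) > 0, d_cost / d_qaly < l)
  }
  expect_error(nmb(1, 1, -5), "non-negative")
})

test_that("PSA draws are reproducible and degenerate distributions collapse to base", {
  p <- default_params(); lt <- base_lifetable()
  psa1 <- run_psa_model(p, lt, n = 25, seed = 5)
  psa2 <- run_psa_model(p, lt, n = 25, seed = 5)
  expect_identical(psa1, psa2)

  p0 <- p; p0$psa$rel_range <- 0
  psa0 <- run_psa_model(p0, lt, n = 5, seed = 9)
  det <- run_base_case(p0, lt)$icer
  expect_equal(psa0$d_cost, rep(det$d_cost, 5), tolerance = 1e-12)
  expect_equal(psa0$d_qaly, rep(det$d_qaly, 5), tolerance = 1e-12)
})

test_that("CEAC probabilities sum to one and behave at the limits", {
  psa <- data.frame(draw = 1:2, d_cost = c(200, 300), d_ly = c(2, 1),
                    d_qaly = c(2, 1))  # ICERs 100 and 300
  ce <- ceac(psa, lambdas = c(0, 200, 1e9))
  expect_equal(ce$p_trastuzumab, c(0, 0.5, 1))
  expect_equal(ce$p_trastuzumab + ce$p_chemo, rep(1, 3))

  p <- default_params(); lt <- base_lifetable()
  psa <- run_psa_model(p, lt, n = 60, seed = 12)
  ce <- ceac(psa, lambdas = seq(0, 2000e6, by = 50e6))
  expect_equal(ce$p_trastuzumab + ce$p_chemo, rep(1, nrow(ce)))
  # all draws in the trade-off quadrant: the curve is non-decreasing
  expect_true(all(psa$d_cost > 0 & psa$d_qaly > 0))
  expect_true(all(diff(ce$p_trastuzumab) >= 0))
  expect_error(ceac(psa[0, ]), "non-empty")
})

test_that("EVPI is the expected opportunity loss and is never negative", {
  one_sided <- data.frame(d_cost = c(10, 20), d_qaly = c(1, 1))
  expect_equal(evpi(one_sided, 100)$per_person, 0)

  two_draw <- data.frame(d_cost = c(-10, 10), d_qaly = c(0, 0))
  expect_equal(evpi(two_draw, 50)$per_person, 5)
  expect_equal(evpi(two_draw, 50, population = 5052)$population, 5 * 5052)

  set.seed(77)
  for (i in 1:10) {
    rnd <- data.frame(d_cost = rnorm(20, 0, 100), d_qaly = rnorm(20, 0, 1))
    expect_gte(evpi(rnd, 150)$per_person, -1e-12)
  }
})

test_that("tornado ranks parameter influence and flags degenerate ranges", {
  p <- default_params(); lt <- base_lifetable()
  tor <- tornado(p, lt,
                 ranges = list(hr_met = list(lo = 0.39, hi = 0.59),
                               u_dfs = list(lo = 0.832 * 0.9, hi = min(1, 0.832 * 1.1)),
                               trast_drug = list(lo = 787384650 * 0.9, hi = 787384650 * 1.1),
                               p_met_base = list(lo = 0.0785, hi = 0.0785)))
  expect_equal(nrow(tor), 4)
  expect_true(all(diff(tor$span[tor$valid & !is.na(tor$span)]) <= 0))
  # the trial CI on the metastasis hazard ratio dominates a 10% utility range
  expect_gt(tor$span[tor$parameter == "hr_met"],
            tor$span[tor$parameter == "u_dfs"])
  # a zero-width range has zero span and sorts last
  expect_equal(tor$span[tor$parameter == "p_met_base"], 0)
  expect_equal(tor$parameter[nrow(tor)], "p_met_base")
  # raising the drug price raises the ICER monotonically
  row <- tor[tor$parameter == "trast_drug", ]
  expect_gt(row$icer_hi, row$icer_lo)
  expect_error(tornado(p, lt, ranges = list(nope = list(lo = 1, hi = 2))),
               "unknown tornado parameter")
})

test_that("threshold price search matches the closed form on the linear cost model", {
  p <- default_params(); lt <- base_lifetable()
  # incremental cost is affine in the price scale s: d_cost(s) = a + b s,
  # d_qaly constant, so s* = (lambda * d_qaly - a) / b is exact
  at_scale <- function(s) {
    p2 <- p
    p2$costs$trast_drug <- p$costs$trast_drug * s
    run_base_case(p2, lt)$icer
  }
  ic0 <- at_scale(0); ic1 <- at_scale(1)
  a <- ic0$d_cost; b <- ic1$d_cost - ic0$d_cost; e <- ic1$d_qaly
  for (lambda in c(83e6, 249e6)) {
    th <- threshold_price(lambda, p, lt, tol = 1e-8)
    s_star <- (lambda * e - a) / b
    expect_equal(th$scale, s_star, tolerance = 1e-6)
    expect_equal(th$achieved_icer, lambda, tolerance = 1e-6)
    expect_equal(th$price_440 / th$price_150,
                 p$costs$p_440 / p$costs$p_150, tolerance = 1e-12)
  }
  # s* shrinks with the threshold
  s1 <- threshold_price(83e6, p, lt)$scale
  s3 <- threshold_price(249e6, p, lt)$scale
  expect_lt(s1, s3)
  # fixed point: if ICER(1) equals lambda already, s* = 1
  lam_now <- ic1$icer_qaly
  expect_equal(threshold_price(lam_now, p, lt, tol = 1e-8)$scale, 1, tolerance = 1e-4)
  # a threshold below the ICER floor (free drug) is reported unreachable
  th0 <- threshold_price(1e4, p, lt)
  expect_false(th0$reachable)
  expect_gt(th0$icer_floor, 1e4)
})

test_that("cost-only changes leave the effect difference bit-identical", {
  p <- default_params(); lt <- base_lifetable()
  base <- run_base_case(p, lt)$icer
  p2 <- p; p2$costs$trast_drug <- p$costs$trast_drug * 0.5
  half <- run_base_case(p2, lt)$icer
  expect_identical(half$d_qaly, base$d_qaly)
  expect_identical(half$d_ly, base$d_ly)
  expect_lt(half$d_cost, base$d_cost)
})

test_that("scenario runner: empty overrides reproduce the base case; sharing lowers cost only", {
  p <- default_params(); lt <- base_lifetable()
  sc <- scenario_run(list(), p, lt, n = 20, seed = 3)
  det <- run_base_case(p, lt)$icer
  expect_equal(sc$base$icer$icer_qaly, det$icer_qaly)
  expect_equal(sc$psa_prob$lambda, c(83e6, 249e6))

  sh <- scenario_run(list(), p, lt, n = 20, seed = 3, sharing = TRUE)
  expect_identical(sh$base$icer$d_qaly, det$d_qaly)
  expect_lt(sh$base$icer$d_cost, det$d_cost)
  expect_equal(sh$therapy_cost$vnd[sh$therapy_cost$component == "drug"],
               p$costs$trast_drug_sharing)

  expect_error(scenario_run(list(bogus = 1), p, lt, n = 5, seed = 1),
               "unknown override key")
})
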