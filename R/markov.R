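#' Health states of the model
#'
#' Fixed state ordering used by every transition matrix and cohort trace:
#' `DFS` (disease-free), `DFS_CHF` (disease-free after a congestive heart
#' failure event), `LRR` (local-regional recurrence), `DFS_POST_LRR`
#' (disease-free after local-regional recurrence), `MET` (metastatic),
#' `DEAD` (absorbing).
#'
#' @export
health_states <- function() c("DFS", "DFS_CHF", "LRR", "DFS_POST_LRR", "MET", "DEAD")

.S <- list(DFS = 1L, DFS_CHF = 2L, LRR = 3L, DFS_POST_LRR = 4L, MET = 5L, DEAD = 6L)

#' Convert an annual probability under a hazard ratio
#'
#' Rate-based survival identity: the annual probability `p` is converted to a
#' hazard, multiplied by `hr`, and converted back, i.e.
#' `1 - (1 - p)^hr`. Valid for any `hr > 0` and guarantees a result in
#' `[0, 1)` for `p < 1`. `method = "linear"` applies `p * hr` directly
#' (capped at 1) for sensitivity to the conversion convention.
#'
#' @param p annual probability in `[0, 1]`.
#' @param hr hazard ratio (> 0).
#' @param method `"rate"` (default) or `"linear"`.
#' @return adjusted annual probability.
#' @export
hr_adjust <- function(p, hr, method = c("rate", "linear")) {
  method <- match.arg(method)
  if (any(p < 0) || any(p > 1)) stop("'p' must lie in [0, 1]")
  if (any(hr <= 0)) stop("'hr' must be strictly positive")
  # hr = 1 returns p bit-exactly (1 - (1 - p) reintroduces rounding)
  if (method == "rate") ifelse(hr == 1, p, 1 - (1 - p)^hr) else pmin(1, p * hr)
}

#' Per-cycle transition matrix for one arm
#'
#' Assembles the 6x6 row-stochastic matrix for the given arm, cycle and age.
#' Background mortality `q = qx(age)` competes first: every disease-event
#' probability is scaled by `(1 - q)` and `q` flows to `DEAD` from every alive
#' state. Arm- and cycle-specific structure:
#'
#' * cardiotoxicity (CHF) occurs only at cycle 0, with the arm's first-year
#'   probability; CHF itself carries no excess mortality;
#' * in the trastuzumab arm, recurrence and metastasis probabilities from
#'   `DFS` are hazard-ratio adjusted for cycles `0 .. benefit_duration - 1`;
#' * no new transitions into `LRR` or `MET` from disease-free states from
#'   cycle `recurrence_cutoff` onward (patients already recurred keep
#'   progressing);
#' * after CHF, recurrence risks revert to the untreated baselines
#'   (trastuzumab is discontinued);
#' * metastatic patients die from disease and background causes as
#'   independent competing risks; cancer death occurs only from `MET`.
#'
#' @param arm `"trastuzumab"` or `"chemo"`.
#' @param cycle cycle index from 0.
#' @param age attained age in years at the start of the cycle.
#' @param params a `her2_params` list.
#' @param lt a `life_table`.
#' @return 6x6 transition matrix with `health_states()` dimnames.
#' @export
build_matrix <- function(arm = c("trastuzumab", "chemo"), cycle, age, params, lt) {
  arm <- match.arg(arm)
  cl <- params$clinical
  st <- params$settings
  q <- qx_at(lt, age)

  trast_active <- arm == "trastuzumab" && cycle < st$benefit_duration
  recur_open <- cycle < st$recurrence_cutoff

  p_chf <- if (cycle == 0) {
    if (arm == "trastuzumab") cl$p_chf_trast else cl$p_chf_chemo
  } else 0
  p_lrr <- if (!recur_open) 0 else if (trast_active) {
    hr_adjust(cl$p_lrr_base, cl$hr_lrr, st$hr_method)
  } else cl$p_lrr_base
  p_met <- if (!recur_open) 0 else if (trast_active) {
    hr_adjust(cl$p_met_base, cl$hr_met, st$hr_method)
  } else cl$p_met_base
  p_lrr_chf <- if (recur_open) cl$p_lrr_chf else 0
  p_met_chf <- if (recur_open) cl$p_met_chf else 0
  p_met_rec <- hr_adjust(cl$p_met_base, cl$rr_met_after_lrr, st$hr_method)

  M <- matrix(0, 6, 6, dimnames = list(health_states(), health_states()))
  fill_row <- function(i, events) {
    # events: named by destination index, pre-mortality probabilities
    ev <- events * (1 - q)
    stay <- 1 - q - sum(ev)
    if (stay < -1e-12) {
      stop(sprintf("negative remainder in state %s at cycle %d: event probabilities sum to %.4f",
                   health_states()[i], cycle, sum(events)))
    }
    M[i, .S$DEAD] <<- q
    for (j in seq_along(ev)) M[i, as.integer(names(ev)[j])] <<- ev[j]
    M[i, i] <<- max(0, stay)
  }
  fill_row(.S$DFS, stats::setNames(c(p_chf, p_lrr, p_met),
                                   c(.S$DFS_CHF, .S$LRR, .S$MET)))
  fill_row(.S$DFS_CHF, stats::setNames(c(p_lrr_chf, p_met_chf), c(.S$LRR, .S$MET)))
  fill_row(.S$LRR, stats::setNames(c(cl$p_dfs_after_lrr, p_met_rec),
                                   c(.S$DFS_POST_LRR, .S$MET)))
  fill_row(.S$DFS_POST_LRR, stats::setNames(p_met_rec, .S$MET))
  # disease and background death as independent competing causes
  M[.S$MET, .S$DEAD] <- 1 - (1 - cl$p_death_met) * (1 - q)
  M[.S$MET, .S$MET] <- 1 - M[.S$MET, .S$DEAD]
  M[.S$DEAD, .S$DEAD] <- 1
  M
}

# Reward vectors in state order (DEAD = 0).
.utility_vector <- function(p) {
  u <- p$utilities
  c(u$u_dfs, u$u_dfs_chf, u$u_lrr, u$u_dfs_post_lrr, u$u_met, 0)
}

.state_cost_vector <- function(p) {
  cc <- p$costs
  c(cc$c_dfs, cc$c_dfs_chf, cc$c_lrr, cc$c_dfs_post_lrr, cc$c_met, 0)
}

#' One-off therapy cost incurred in the first model year
#'
#' Trastuzumab arm: drug cost (printed aggregate or the vial calculator,
#' per `settings$drug_cost_mode` and `sharing`), HER2 detection, other direct
#' medical and direct non-medical costs, plus the drug-only paclitaxel cost of
#' the concurrent chemotherapy. Chemotherapy arm: the full paclitaxel
#' treatment cost.
#'
#' @param arm `"trastuzumab"` or `"chemo"`.
#' @param params a `her2_params` list.
#' @param sharing use the vial-sharing drug cost (scenario analysis).
#' @return cost in VND.
#' @export
year_one_cost <- function(arm = c("trastuzumab", "chemo"), params, sharing = FALSE) {
  arm <- match.arg(arm)
  cc <- params$costs
  if (arm == "chemo") return(cc$paclitaxel_treatment)
  drug <- trast_drug_cost(params, sharing = sharing)
  drug + cc$her2_detection + cc$trast_other_direct_medical +
    cc$trast_direct_nonmedical + cc$paclitaxel_drug_only
}

#' Run the Markov cohort simulation for one arm
#'
#' The cohort enters fully disease-free at `start_age`. At each annual cycle
#' `t`, rewards accrue on start-of-cycle occupancy (life years on the alive
#' fraction, QALYs via state utilities, costs via annual state costs),
#' discounted by `(1 + r)^-t`; the arm's one-off first-year therapy cost is
#' added at `t = 0` undiscounted; the transition matrix is then applied. The
#' simulation stops at `max_age` or when the alive fraction falls below
#' 1e-12. With `half_cycle_correction = TRUE`, state rewards accrue on the
#' average of start- and end-of-cycle occupancy instead.
#'
#' @param arm `"trastuzumab"` or `"chemo"`.
#' @param params a `her2_params` list.
#' @param lt a `life_table`.
#' @param sharing use the vial-sharing drug cost in the trastuzumab arm.
#' @return an `arm_result` list: `per_person` and `cohort` discounted and
#'   undiscounted totals (`cost`, `ly`, `qaly`), and the `trace` data.frame
#'   (cycle, age, six state occupancies, discounted per-cycle increments).
#' @export
run_cohort <- function(arm = c("trastuzumab", "chemo"), params, lt, sharing = FALSE) {
  arm <- match.arg(arm)
  validate_params(params)
  validate_life_table(lt)
  st <- params$settings
  r <- st$discount_rate
  u <- .utility_vector(params)
  cvec <- .state_cost_vector(params)
  hcc <- isTRUE(st$half_cycle_correction)
  horizon <- st$max_age - st$start_age

  occ <- c(1, 0, 0, 0, 0, 0)
  cost_d <- ly_d <- qaly_d <- cost_u <- ly_u <- qaly_u <- 0
  one_off <- year_one_cost(arm, params, sharing = sharing)
  cost_d <- cost_u <- one_off

  tr <- vector("list", horizon)
  t <- 0L
  while (t < horizon && sum(occ[1:5]) >= 1e-12) {
    age <- st$start_age + t
    M <- build_matrix(arm, t, age, params, lt)
    occ_next <- as.numeric(occ %*% M)
    basis <- if (hcc) (occ + occ_next) / 2 else occ
    disc <- (1 + r)^(-t)
    d_ly <- sum(basis[1:5]); d_q <- sum(basis * u); d_c <- sum(basis * cvec)
    ly_d <- ly_d + disc * d_ly; qaly_d <- qaly_d + disc * d_q; cost_d <- cost_d + disc * d_c
    ly_u <- ly_u + d_ly; qaly_u <- qaly_u + d_q; cost_u <- cost_u + d_c
    tr[[t + 1L]] <- c(t, age, occ, disc * d_c, disc * d_ly, disc * d_q)
    occ <- occ_next
    t <- t + 1L
  }
  trace <- as.data.frame(do.call(rbind, tr[seq_len(t)]))
  names(trace) <- c("cycle", "age", health_states(), "cost_disc", "ly_disc", "qaly_disc")

  pp <- list(cost = cost_d, ly = ly_d, qaly = qaly_d,
             cost_undisc = cost_u, ly_undisc = ly_u, qaly_undisc = qaly_u)
  structure(list(
    arm = arm,
    per_person = pp,
    cohort = lapply(pp, function(x) x * st$cohort_size),
    trace = trace
  ), class = "arm_result")
}

#' @export
print.arm_result <- function(x, ...) {
  cat(sprintf("Arm: %s\n", x$arm))
  cat(sprintf("Per person (discounted): cost %.0f VND, %.4f LY, %.4f QALY\n",
              x$per_person$cost, x$per_person$ly, x$per_person$qaly))
  invisible(x)
}

#' Individual-level microsimulation oracle
#'
#' Simulates `n_individuals` independent trajectories with exactly the same
#' per-cycle transition matrices, reward accrual and discounting conventions
#' as [run_cohort()], and returns Monte-Carlo estimates with standard errors.
#' Serves as an independent check of the cohort engine: each estimate is
#' unbiased for the corresponding cohort-engine total.
#'
#' @inheritParams run_cohort
#' @param n_individuals number of simulated patients.
#' @param seed integer RNG seed.
#' @return list with `mean` and `se` (each with `cost`, `ly`, `qaly`,
#'   discounted, per person) and `n`.
#' @export
microsim <- function(arm = c("trastuzumab", "chemo"), params, lt,
                     n_individuals, seed, sharing = FALSE) {
  arm <- match.arg(arm)
  validate_params(params)
  if (n_individuals < 1) stop("n_individuals must be >= 1")
  st <- params$settings
  r <- st$discount_rate
  u <- .utility_vector(params)
  cvec <- .state_cost_vector(params)
  horizon <- st$max_age - st$start_age
  if (isTRUE(st$half_cycle_correction)) {
    stop("microsim supports start-of-cycle accrual only (half_cycle_correction = FALSE)")
  }

  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  n <- n_individuals
  state <- rep(1L, n)
  cost <- rep(year_one_cost(arm, params, sharing = sharing), n)
  ly <- qaly <- rep(0, n)
  for (t in seq_len(horizon) - 1L) {
    alive <- state != .S$DEAD
    if (!any(alive)) break
    disc <- (1 + r)^(-t)
    ly[alive] <- ly[alive] + disc
    qaly <- qaly + disc * u[state]
    cost <- cost + disc * cvec[state]
    M <- build_matrix(arm, t, st$start_age + t, params, lt)
    # draw from the pre-cycle state snapshot so nobody transitions twice
    prev <- state
    for (s in 1:5) {
      idx <- which(prev == s)
      if (length(idx)) {
        state[idx] <- sample.int(6L, length(idx), replace = TRUE, prob = M[s, ])
      }
    }
  }
  list(
    mean = list(cost = mean(cost), ly = mean(ly), qaly = mean(qaly)),
    se = list(cost = stats::sd(cost) / sqrt(n), ly = stats::sd(ly) / sqrt(n),
              qaly = stats::sd(qaly) / sqrt(n)),
    n = n
  )
}
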