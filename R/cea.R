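#' Incremental cost-effectiveness ratio between two arms
#'
#' Computes per-person and cohort-scaled incremental cost, life years and
#' QALYs (reference minus comparator) and the ICERs per LY and per QALY in
#' VND and US$. Dominance is classified from the incremental quadrant:
#' `"dominant"` (cheaper and at least as effective), `"dominated"` (costlier
#' and no more effective), `"trade-off"` otherwise; an ICER is reported only
#' for trade-offs. A zero QALY difference with a non-zero cost difference is
#' flagged `undefined = TRUE` rather than erroring.
#'
#' @param reference,comparator `arm_result` objects from [run_cohort()] run
#'   under identical settings.
#' @param params the `her2_params` the arms were run with (for exchange rate
#'   and cohort size).
#' @return an `icer_result` list.
#' @export
icer <- function(reference, comparator, params) {
  rp <- reference$per_person; cp <- comparator$per_person
  d_cost <- rp$cost - cp$cost
  d_ly <- rp$ly - cp$ly
  d_qaly <- rp$qaly - cp$qaly
  rate <- params$settings$exchange_rate
  n <- params$settings$cohort_size

  dominance <- if (d_qaly > 0 && d_cost <= 0) "dominant"
  else if (d_qaly <= 0 && d_cost >= 0 && !(d_qaly == 0 && d_cost == 0)) "dominated"
  else "trade-off"
  undefined <- d_qaly == 0 && d_cost != 0

  icer_qaly <- if (dominance == "trade-off" && d_qaly != 0) d_cost / d_qaly else NA_real_
  icer_ly <- if (dominance == "trade-off" && d_ly != 0) d_cost / d_ly else NA_real_

  structure(list(
    d_cost = d_cost, d_ly = d_ly, d_qaly = d_qaly,
    d_cost_usd = vnd_to_usd(d_cost, rate),
    cohort = list(d_cost = d_cost * n, d_ly = d_ly * n, d_qaly = d_qaly * n),
    icer_qaly = icer_qaly, icer_ly = icer_ly,
    icer_qaly_usd = if (is.na(icer_qaly)) NA_real_ else vnd_to_usd(icer_qaly, rate),
    icer_ly_usd = if (is.na(icer_ly)) NA_real_ else vnd_to_usd(icer_ly, rate),
    dominance = dominance, undefined = undefined
  ), class = "icer_result")
}

#' @export
print.icer_result <- function(x, ...) {
  cat(sprintf("Incremental: cost %.0f VND (%.0f US$), %.4f LY, %.4f QALY [%s]\n",
              x$d_cost, x$d_cost_usd, x$d_ly, x$d_qaly, x$dominance))
  if (!is.na(x$icer_qaly)) {
    cat(sprintf("ICER: %.0f VND (%.0f US$) per QALY; %.0f VND (%.0f US$) per LY\n",
                x$icer_qaly, x$icer_qaly_usd, x$icer_ly, x$icer_ly_usd))
  }
  invisible(x)
}

#' Net monetary benefit
#'
#' `lambda * QALY - cost`. Applied to an increment, a positive value is
#' equivalent to the ICER lying below `lambda` (for a positive QALY gain).
#'
#' @param cost cost in VND (vectorised).
#' @param qaly QALYs.
#' @param lambda willingness to pay, VND per QALY (>= 0).
#' @return NMB in VND.
#' @export
nmb <- function(cost, qaly, lambda) {
  if (any(lambda < 0)) stop("'lambda' must be non-negative")
  lambda * qaly - cost
}

#' Deterministic base-case comparison
#'
#' Runs both arms and returns their results with the ICER.
#'
#' @param params a `her2_params` list.
#' @param lt a `life_table`.
#' @param sharing vial-sharing drug cost in the trastuzumab arm?
#' @return list with `trastuzumab`, `chemo` (`arm_result`) and `icer`.
#' @export
run_base_case <- function(params, lt, sharing = FALSE) {
  tr <- run_cohort("trastuzumab", params, lt, sharing = sharing)
  ch <- run_cohort("chemo", params, lt)
  list(trastuzumab = tr, chemo = ch, icer = icer(tr, ch, params))
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n` joint parameter samples with [sample_psa()] and, for each draw,
#' runs both arms with the same resolved parameter values (arm differences
#' enter only through the model structure), recording the per-person
#' incremental cost, LYs and QALYs. Reproducible under `seed`.
#'
#' @param params a `her2_params` list.
#' @param lt a `life_table`.
#' @param n number of Monte-Carlo iterations.
#' @param seed integer RNG seed.
#' @param sharing vial-sharing drug cost in the trastuzumab arm?
#' @return data.frame with columns `draw`, `d_cost`, `d_ly`, `d_qaly`; the
#'   sampled parameters are attached as `attr(, "samples")`.
#' @export
run_psa_model <- function(params, lt, n = params$psa$n_iterations,
                          seed = 20240315, sharing = FALSE) {
  samples <- sample_psa(params, n, seed)
  d_cost <- d_ly <- d_qaly <- numeric(n)
  for (i in seq_len(n)) {
    pi <- .apply_draw(params, samples[i, , drop = FALSE])
    res <- run_base_case(pi, lt, sharing = sharing)
    d_cost[i] <- res$icer$d_cost
    d_ly[i] <- res$icer$d_ly
    d_qaly[i] <- res$icer$d_qaly
  }
  out <- data.frame(draw = seq_len(n), d_cost = d_cost, d_ly = d_ly, d_qaly = d_qaly)
  attr(out, "samples") <- samples
  out
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value, the probability that the trastuzumab
#' strategy is cost-effective is the fraction of PSA draws with positive
#' incremental net monetary benefit (ties favour the comparator); the
#' chemotherapy probability is its complement, so the two sum to one.
#'
#' @param psa data.frame from [run_psa_model()].
#' @param lambdas willingness-to-pay grid, VND per QALY (default 0 to 1,000
#'   million in 5-million steps).
#' @return data.frame with columns `lambda`, `p_trastuzumab`, `p_chemo`.
#' @export
ceac <- function(psa, lambdas = seq(0, 1000e6, by = 5e6)) {
  if (nrow(psa) == 0 || length(lambdas) == 0) stop("ceac requires non-empty draws and lambda grid")
  p <- vapply(lambdas, function(l) mean(nmb(psa$d_cost, psa$d_qaly, l) > 0), numeric(1))
  data.frame(lambda = lambdas, p_trastuzumab = p, p_chemo = 1 - p)
}

#' Expected value of perfect information
#'
#' Per person: `mean(max(0, iNMB)) - max(0, mean(iNMB))` over the PSA draws —
#' the expected gain of deciding with, rather than without, perfect knowledge
#' of the parameters. Always non-negative, and zero when the same arm wins in
#' every draw. Population EVPI scales by `population` (one annual treatment
#' cohort).
#'
#' @param psa data.frame from [run_psa_model()].
#' @param lambda willingness to pay, VND per QALY.
#' @param population persons affected by the decision (default 1).
#' @return list with `per_person` and `population` EVPI in VND.
#' @export
evpi <- function(psa, lambda, population = 1) {
  if (nrow(psa) == 0) stop("evpi requires non-empty draws")
  if (lambda < 0) stop("'lambda' must be non-negative")
  inmb <- nmb(psa$d_cost, psa$d_qaly, lambda)
  pp <- mean(pmax(0, inmb)) - max(0, mean(inmb))
  list(per_person = pp, population = pp * population)
}

# Default one-way ranges: the PSA uncertainty spec's (lo, hi) intervals.
.tornado_ranges <- function(params) {
  spec <- .psa_spec(params)
  lapply(spec, function(sp) list(section = sp$section, base = sp$base,
                                 lo = sp$lo, hi = sp$hi))
}

#' One-way (tornado) sensitivity analysis
#'
#' Recomputes the deterministic ICER per QALY with each parameter set to the
#' low and high end of its range, all others held at base. Entries are sorted
#' by descending ICER span. A range end that produces an invalid model is
#' flagged (`valid = FALSE`) with `NA` for that ICER rather than aborting the
#' analysis.
#'
#' @param params a `her2_params` list.
#' @param lt a `life_table`.
#' @param ranges named list of `list(lo =, hi =)` overrides; defaults to the
#'   PSA uncertainty ranges (published CIs where configured, otherwise
#'   +/- 10%).
#' @param sharing vial-sharing drug cost in the trastuzumab arm?
#' @return data.frame: `parameter`, `lo`, `hi`, `icer_lo`, `icer_hi`, `span`,
#'   `valid`, sorted by descending span.
#' @export
tornado <- function(params, lt, ranges = NULL, sharing = FALSE) {
  spec <- .tornado_ranges(params)
  if (!is.null(ranges)) {
    for (nm in names(ranges)) {
      if (!nm %in% names(spec)) stop("unknown tornado parameter: ", nm)
      spec[[nm]]$lo <- ranges[[nm]]$lo
      spec[[nm]]$hi <- ranges[[nm]]$hi
    }
    spec <- spec[names(ranges)]
  }
  eval_at <- function(nm, value) {
    p2 <- params
    p2[[spec[[nm]]$section]][[nm]] <- value
    tryCatch(run_base_case(p2, lt, sharing = sharing)$icer$icer_qaly,
             error = function(e) NA_real_)
  }
  rows <- lapply(names(spec), function(nm) {
    sp <- spec[[nm]]
    if (!(sp$lo <= sp$base && sp$base <= sp$hi)) {
      stop(sprintf("tornado range for '%s' must satisfy lo <= base <= hi", nm))
    }
    lo_icer <- eval_at(nm, sp$lo)
    hi_icer <- eval_at(nm, sp$hi)
    data.frame(parameter = nm, lo = sp$lo, hi = sp$hi,
               icer_lo = lo_icer, icer_hi = hi_icer,
               span = abs(hi_icer - lo_icer),
               valid = !is.na(lo_icer) && !is.na(hi_icer))
  })
  out <- do.call(rbind, rows)
  out$span[is.na(out$span)] <- -Inf
  out <- out[order(-out$span), ]
  out$span[!is.finite(out$span)] <- NA_real_
  rownames(out) <- NULL
  out
}

#' Threshold price of trastuzumab at a willingness-to-pay value
#'
#' Finds the common multiplicative factor `s*` applied to both vial prices
#' (and hence to the drug-cost aggregate, which is proportional to them) at
#' which the deterministic ICER per QALY equals `lambda`, by bisection to
#' `|ICER(s) - lambda| <= tol * lambda`. If the ICER with free drug
#' (`s = 0`) still exceeds `lambda`, the threshold is unreachable and the
#' ICER floor is reported instead.
#'
#' @param lambda willingness to pay, VND per QALY.
#' @param params a `her2_params` list.
#' @param lt a `life_table`.
#' @param sharing search under the vial-sharing drug cost?
#' @param tol relative ICER tolerance (default 1e-4, i.e. 0.01% of `lambda`).
#' @return a `threshold_result` list: `lambda`, `scale`, `price_440`,
#'   `price_150`, `achieved_icer`, `reachable` (and `icer_floor` when
#'   unreachable).
#' @export
threshold_price <- function(lambda, params, lt, sharing = FALSE, tol = 1e-4) {
  if (lambda <= 0) stop("'lambda' must be strictly positive")
  base_drug <- trast_drug_cost(params, sharing = sharing)
  icer_at <- function(s) {
    p2 <- params
    p2$settings$drug_cost_mode <- "printed"
    p2$costs$trast_drug <- base_drug * s
    p2$costs$trast_drug_sharing <- base_drug * s
    run_base_case(p2, lt)$icer$icer_qaly
  }
  floor_icer <- icer_at(0)
  if (!is.na(floor_icer) && floor_icer > lambda) {
    return(structure(list(lambda = lambda, scale = NA_real_,
                          price_440 = NA_real_, price_150 = NA_real_,
                          achieved_icer = NA_real_, reachable = FALSE,
                          icer_floor = floor_icer), class = "threshold_result"))
  }
  hi <- 1
  while (icer_at(hi) < lambda && hi < 1e6) hi <- hi * 2
  lo <- 0
  repeat {
    mid <- (lo + hi) / 2
    ic <- icer_at(mid)
    if (abs(ic - lambda) <= tol * lambda) break
    if (ic > lambda) hi <- mid else lo <- mid
    if (hi - lo < 1e-15) break
  }
  structure(list(lambda = lambda, scale = mid,
                 price_440 = params$costs$p_440 * mid,
                 price_150 = params$costs$p_150 * mid,
                 achieved_icer = ic, reachable = TRUE),
            class = "threshold_result")
}

#' Scenario analysis
#'
#' Re-runs the deterministic comparison, the PSA (with cost-effectiveness
#' probabilities at the configured willingness-to-pay thresholds), and the
#' threshold price search under named parameter overrides — e.g. the
#' vial-sharing scenario via `sharing = TRUE`, which substitutes the sharing
#' drug cost. Empty overrides reproduce the base case.
#'
#' @param overrides named list of parameter substitutions (keys as in the
#'   configuration sections); unknown keys error.
#' @param params a `her2_params` list.
#' @param lt a `life_table`.
#' @param n PSA iterations (default from `params$psa$n_iterations`).
#' @param seed integer RNG seed.
#' @param sharing vial-sharing drug cost in the trastuzumab arm?
#' @return a `scenario_result` list: `base` (deterministic results),
#'   `therapy_cost` breakdown, `psa_prob` (probability cost-effective at each
#'   threshold), and `thresholds` (threshold prices at each threshold).
#' @export
scenario_run <- function(overrides = list(), params, lt,
                         n = params$psa$n_iterations, seed = 20240315,
                         sharing = FALSE) {
  sections <- c("clinical", "utilities", "costs", "settings")
  for (nm in names(overrides)) {
    hit <- sections[vapply(sections, function(s) nm %in% names(params[[s]]), logical(1))]
    if (length(hit) == 0) stop("unknown override key: ", nm)
    params[[hit[1]]][[nm]] <- overrides[[nm]]
  }
  validate_params(params)
  base <- run_base_case(params, lt, sharing = sharing)
  psa <- run_psa_model(params, lt, n = n, seed = seed, sharing = sharing)
  wtp <- params$settings$wtp_thresholds
  prob <- vapply(wtp, function(l) mean(nmb(psa$d_cost, psa$d_qaly, l) > 0), numeric(1))
  thr <- lapply(wtp, threshold_price, params = params, lt = lt, sharing = sharing)
  structure(list(
    base = base,
    therapy_cost = therapy_cost_breakdown(params, sharing = sharing),
    psa = psa,
    psa_prob = data.frame(lambda = wtp, p_cost_effective = prob),
    thresholds = thr
  ), class = "scenario_result")
}
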