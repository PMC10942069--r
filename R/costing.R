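#' Trastuzumab dosing schedule
#'
#' Weight-based intravenous dosing: a loading dose followed by maintenance
#' doses at a fixed interval for the treatment duration (default 8 mg/kg then
#' 6 mg/kg every 3 weeks for one year).
#'
#' @param loading loading dose, mg/kg.
#' @param maintenance maintenance dose, mg/kg.
#' @param interval_weeks weeks between administrations.
#' @param duration_weeks total treatment duration in weeks.
#' @return a `dose_schedule` list.
#' @export
dose_schedule <- function(loading = 8, maintenance = 6,
                          interval_weeks = 3, duration_weeks = 52) {
  if (loading <= 0 || maintenance <= 0) stop("doses must be strictly positive")
  if (interval_weeks <= 0 || duration_weeks <= 0) stop("interval and duration must be positive")
  structure(list(loading = loading, maintenance = maintenance,
                 interval_weeks = interval_weeks, duration_weeks = duration_weeks),
            class = "dose_schedule")
}

.schedule_from_params <- function(params) {
  s <- params$settings
  dose_schedule(s$dose_loading, s$dose_maintenance,
                s$dose_interval_weeks, s$dose_duration_weeks)
}

#' Number of administrations over the treatment course
#'
#' Doses are given at weeks `0, interval, 2*interval, ...` strictly before
#' `duration_weeks`; the default 3-weekly/52-week schedule gives 18 (one
#' loading plus 17 maintenance doses).
#'
#' @param schedule a [dose_schedule()].
#' @return integer count.
#' @export
doses_per_year <- function(schedule = dose_schedule()) {
  # administrations at weeks 0, interval, ..., strictly before duration
  as.integer(ceiling(schedule$duration_weeks / schedule$interval_weeks - 1e-12))
}

# mg required at each administration for a given body weight
.dose_mg <- function(weight, schedule) {
  k <- doses_per_year(schedule)
  c(schedule$loading, rep(schedule$maintenance, k - 1)) * weight
}

#' Vial specifications
#'
#' @param size vial sizes in mg.
#' @param price prices in VND per vial.
#' @return data.frame with columns `size`, `price`.
#' @export
vial_specs <- function(size = c(440, 150), price) {
  if (length(size) == 0) stop("at least one vial specification is required")
  if (any(size <= 0) || any(price < 0)) stop("vial sizes must be positive and prices non-negative")
  data.frame(size = size, price = price)
}

.vials_from_params <- function(params) {
  vial_specs(c(440, 150), c(params$costs$p_440, params$costs$p_150))
}

# Cheapest integer vial combination covering `req` mg (exhaustive search).
.cheapest_cover <- function(req, vials) {
  maxn <- ceiling(req / vials$size)
  grids <- lapply(maxn, function(m) 0:m)
  combos <- as.matrix(expand.grid(grids))
  mg <- combos %*% vials$size
  cost <- combos %*% vials$price
  ok <- mg >= req & mg > 0
  min(cost[ok])
}

#' Annual trastuzumab drug cost without vial sharing
#'
#' For every administration the required dose (mg/kg x weight) is covered by
#' the cheapest integer combination of vials (exhaustive search); partial-vial
#' remainders are discarded. Costs are summed over all administrations in the
#' course.
#'
#' @param weight patient weight in kg.
#' @param schedule a [dose_schedule()].
#' @param vials a [vial_specs()] data.frame.
#' @return annual drug cost in VND.
#' @export
drug_cost_no_sharing <- function(weight, schedule = dose_schedule(),
                                 vials = vial_specs(price = c(45596775, 15550710))) {
  if (weight <= 0) stop("'weight' must be strictly positive")
  if (nrow(vials) == 0) stop("empty vial set")
  doses <- .dose_mg(weight, schedule)
  per_dose <- vapply(unique(doses), .cheapest_cover, numeric(1), vials = vials)
  names(per_dose) <- unique(doses)
  sum(per_dose[as.character(doses)])
}

#' Annual trastuzumab drug cost with ideal vial sharing
#'
#' With concurrent patients sharing vials, partial-vial remainders are never
#' wasted: the cost is the total milligrams required over the course times the
#' cheapest available price per mg. A lower bound on (and never more than)
#' the no-sharing cost.
#'
#' @inheritParams drug_cost_no_sharing
#' @return annual drug cost in VND.
#' @export
drug_cost_sharing <- function(weight, schedule = dose_schedule(),
                              vials = vial_specs(price = c(45596775, 15550710))) {
  if (weight <= 0) stop("'weight' must be strictly positive")
  if (nrow(vials) == 0) stop("empty vial set")
  total_mg <- sum(.dose_mg(weight, schedule))
  total_mg * min(vials$price / vials$size)
}

#' Trastuzumab drug cost used by the model
#'
#' `settings$drug_cost_mode = "printed"` uses the configured cost aggregates
#' (`trast_drug`, and `trast_drug_sharing` for the sharing scenario);
#' `"computed"` derives them from the vial calculator at the configured
#' patient weight, schedule and vial prices.
#'
#' @param params a `her2_params` list.
#' @param sharing vial-sharing scenario?
#' @return drug cost in VND.
#' @export
trast_drug_cost <- function(params, sharing = FALSE) {
  if (params$settings$drug_cost_mode == "printed") {
    if (!sharing) return(params$costs$trast_drug)
    if (!is.null(params$costs$trast_drug_sharing)) return(params$costs$trast_drug_sharing)
  }
  f <- if (sharing) drug_cost_sharing else drug_cost_no_sharing
  f(params$settings$patient_weight, .schedule_from_params(params), .vials_from_params(params))
}

#' Total one-year therapy cost from its components
#'
#' Exact integer sum of the cost components (VND amounts are integral, so the
#' sum carries no floating-point drift below 2^53).
#'
#' @param components numeric vector or list of component costs in VND.
#' @return total in VND.
#' @export
therapy_cost_total <- function(components) {
  x <- unlist(components)
  if (any(x < 0)) stop("cost components must be non-negative")
  sum(x)
}

#' Per-person one-year trastuzumab therapy cost breakdown
#'
#' @param params a `her2_params` list.
#' @param sharing vial-sharing scenario?
#' @return data.frame of components (VND and US$) plus the total.
#' @export
therapy_cost_breakdown <- function(params, sharing = FALSE) {
  cc <- params$costs
  comp <- c(drug = trast_drug_cost(params, sharing = sharing),
            her2_detection = cc$her2_detection,
            other_direct_medical = cc$trast_other_direct_medical,
            direct_nonmedical = cc$trast_direct_nonmedical)
  out <- data.frame(component = c(names(comp), "total"),
                    vnd = c(comp, therapy_cost_total(comp)))
  out$usd <- vnd_to_usd(out$vnd, params$settings$exchange_rate)
  out
}

#' Convert VND to US$
#'
#' @param amount amount in VND (vectorised).
#' @param rate exchange rate, VND per US$.
#' @param rounded round to the nearest dollar (reporting convention)?
#' @return amount in US$.
#' @export
vnd_to_usd <- function(amount, rate = 22745, rounded = TRUE) {
  if (rate <= 0) stop("'rate' must be strictly positive")
  x <- amount / rate
  if (rounded) round(x) else x
}

#' Price reduction from a current to a target price
#'
#' `100 * (1 - target/current)`, rounded to the nearest integer percent. A
#' target above the current price yields a negative value (a price increase),
#' which is reported rather than treated as an error.
#'
#' @param current current price (> 0).
#' @param target target price (>= 0).
#' @return reduction in percent.
#' @export
price_reduction_percent <- function(current, target) {
  if (any(current <= 0)) stop("'current' must be strictly positive")
  if (any(target < 0)) stop("'target' must be non-negative")
  round(100 * (1 - target / current))
}
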