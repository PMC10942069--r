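#' Parameter sets for the trastuzumab cost-effectiveness model
#'
#' A `her2_params` object is a validated list with five sections mirroring the
#' model's input table: `clinical` (hazard ratios and annual transition
#' probabilities), `utilities` (state utility weights), `costs` (2020 VND),
#' `settings` (cohort and analysis settings) and `psa` (uncertainty
#' specifications used by [sample_psa()] and [tornado()]).
#'
#' @name her2_params
NULL

# Required keys per section; optional keys get documented defaults in
# .apply_param_defaults().
.required_keys <- list(
  clinical = c("hr_dfs", "hr_lrr", "hr_met", "p_lrr_base", "p_met_base",
               "p_dfs_after_lrr", "rr_met_after_lrr", "p_chf_trast",
               "p_chf_chemo", "p_death_met"),
  utilities = c("u_dfs", "u_lrr", "u_dfs_post_lrr", "u_dfs_chf", "u_met"),
  costs = c("trast_drug", "her2_detection", "trast_other_direct_medical",
            "trast_direct_nonmedical", "paclitaxel_treatment",
            "c_dfs", "c_lrr", "c_dfs_post_lrr", "c_met", "c_dfs_chf",
            "p_440", "p_150"),
  settings = c("start_age", "patient_weight", "cohort_size"),
  psa = character(0)
)

.optional_keys <- list(
  clinical = c("p_lrr_chf", "p_met_chf"),
  utilities = character(0),
  costs = c("paclitaxel_drug_only", "trast_drug_sharing"),
  settings = c("max_age", "cycle_length", "discount_rate", "benefit_duration",
               "recurrence_cutoff", "half_cycle_correction", "hr_method",
               "drug_cost_mode", "exchange_rate", "wtp_thresholds",
               "dose_loading", "dose_maintenance", "dose_interval_weeks",
               "dose_duration_weeks"),
  psa = c("n_iterations", "rel_range", "hr_lrr_ci", "hr_met_ci",
          "rr_met_after_lrr_ci")
)

.apply_param_defaults <- function(p) {
  s <- p$settings
  def <- function(cur, val) if (is.null(cur)) val else cur
  s$max_age               <- def(s$max_age, 100)
  s$cycle_length          <- def(s$cycle_length, 1)
  s$discount_rate         <- def(s$discount_rate, 0.03)
  s$benefit_duration      <- def(s$benefit_duration, 5)
  s$recurrence_cutoff     <- def(s$recurrence_cutoff, 20)
  s$half_cycle_correction <- def(s$half_cycle_correction, FALSE)
  s$hr_method             <- def(s$hr_method, "rate")
  s$drug_cost_mode        <- def(s$drug_cost_mode, "printed")
  s$exchange_rate         <- def(s$exchange_rate, 22745)
  s$wtp_thresholds        <- def(s$wtp_thresholds, c(83e6, 249e6))
  s$dose_loading          <- def(s$dose_loading, 8)
  s$dose_maintenance      <- def(s$dose_maintenance, 6)
  s$dose_interval_weeks   <- def(s$dose_interval_weeks, 3)
  s$dose_duration_weeks   <- def(s$dose_duration_weeks, 52)
  p$settings <- s

  # Recurrence risk after first-year cardiotoxicity: trastuzumab is stopped
  # after a CHF event, so the untreated baselines are the default.
  if (is.null(p$clinical$p_lrr_chf)) p$clinical$p_lrr_chf <- p$clinical$p_lrr_base
  if (is.null(p$clinical$p_met_chf)) p$clinical$p_met_chf <- p$clinical$p_met_base
  # Drug-only paclitaxel cost in the combination arm is not published
  # separately; defaulting to the full treatment cost makes it cancel in the
  # increment.
  if (is.null(p$costs$paclitaxel_drug_only)) {
    p$costs$paclitaxel_drug_only <- p$costs$paclitaxel_treatment
  }
  if (is.null(p$psa)) p$psa <- list()
  p$psa$n_iterations <- def(p$psa$n_iterations, 10000)
  p$psa$rel_range    <- def(p$psa$rel_range, 0.10)
  p
}

#' Validate a model parameter set
#'
#' Checks section/key completeness, probability and utility bounds, positivity
#' of ratios and non-negativity of costs, and settings coherence
#' (`benefit_duration <= recurrence_cutoff <= horizon`). Errors name the
#' offending field.
#'
#' @param p a `her2_params` list (see [default_params()]).
#' @return `p`, invisibly, if valid.
#' @export
validate_params <- function(p) {
  secs <- names(.required_keys)
  missing_sec <- setdiff(c("clinical", "utilities", "costs", "settings"), names(p))
  if (length(missing_sec)) {
    stop("parameter set is missing section(s): ", paste(missing_sec, collapse = ", "))
  }
  for (sec in secs) {
    keys <- names(p[[sec]])
    miss <- setdiff(.required_keys[[sec]], keys)
    if (length(miss)) {
      stop(sprintf("missing key(s) in [%s]: %s", sec, paste(miss, collapse = ", ")))
    }
    unknown <- setdiff(keys, c(.required_keys[[sec]], .optional_keys[[sec]]))
    if (length(unknown)) {
      stop(sprintf("unknown key(s) in [%s]: %s", sec, paste(unknown, collapse = ", ")))
    }
  }
  chk_prob <- function(x, nm) {
    if (!is.numeric(x) || is.na(x) || x < 0 || x > 1) {
      stop(sprintf("'%s' must be a probability in [0, 1], got %s", nm, format(x)))
    }
  }
  chk_pos <- function(x, nm) {
    if (!is.numeric(x) || is.na(x) || x <= 0) {
      stop(sprintf("'%s' must be strictly positive, got %s", nm, format(x)))
    }
  }
  chk_nonneg <- function(x, nm) {
    if (!is.numeric(x) || is.na(x) || x < 0) {
      stop(sprintf("'%s' must be non-negative, got %s", nm, format(x)))
    }
  }
  cl <- p$clinical
  for (nm in c("p_lrr_base", "p_met_base", "p_dfs_after_lrr", "p_chf_trast",
               "p_chf_chemo", "p_death_met", "p_lrr_chf", "p_met_chf")) {
    chk_prob(cl[[nm]], nm)
  }
  for (nm in c("hr_dfs", "hr_lrr", "hr_met", "rr_met_after_lrr")) chk_pos(cl[[nm]], nm)
  for (nm in names(p$utilities)) chk_prob(p$utilities[[nm]], nm)
  for (nm in setdiff(names(p$costs), "trast_drug_sharing")) chk_nonneg(p$costs[[nm]], nm)
  if (!is.null(p$costs$trast_drug_sharing)) chk_nonneg(p$costs$trast_drug_sharing, "trast_drug_sharing")

  s <- p$settings
  chk_nonneg(s$discount_rate, "discount_rate")
  chk_pos(s$cycle_length, "cycle_length")
  chk_pos(s$exchange_rate, "exchange_rate")
  chk_pos(s$patient_weight, "patient_weight")
  chk_nonneg(s$cohort_size, "cohort_size")
  horizon <- s$max_age - s$start_age
  if (s$benefit_duration > s$recurrence_cutoff || s$recurrence_cutoff > horizon) {
    stop("settings must satisfy benefit_duration <= recurrence_cutoff <= horizon (max_age - start_age)")
  }
  if (!s$hr_method %in% c("rate", "linear")) stop("'hr_method' must be \"rate\" or \"linear\"")
  if (!s$drug_cost_mode %in% c("printed", "computed")) {
    stop("'drug_cost_mode' must be \"printed\" or \"computed\"")
  }
  invisible(p)
}

#' Base-case parameter set
#'
#' The published base case: trial hazard ratios (disease-free survival 0.760,
#' local-regional recurrence 0.580, metastasis 0.480), annual baseline
#' transition probabilities, EQ-5D-5L utility weights, 2020 VND societal
#' costs, Herceptin vial prices, and analysis settings (cohort of 5,052 women
#' entering disease-free at age 50, annual cycles to age 100, 3%/year
#' discounting of costs and effects, 22,745 VND/US$, willingness-to-pay
#' thresholds of 83 and 249 million VND/QALY).
#'
#' @return a validated `her2_params` list.
#' @export
default_params <- function() {
  p <- list(
    clinical = list(
      hr_dfs = 0.760, hr_lrr = 0.580, hr_met = 0.480,
      p_lrr_base = 0.0294, p_met_base = 0.0785,
      p_dfs_after_lrr = 0.100, rr_met_after_lrr = 3.640,
      p_chf_trast = 0.198, p_chf_chemo = 0.007,
      p_death_met = 0.295
    ),
    utilities = list(
      u_dfs = 0.832, u_lrr = 0.828, u_dfs_post_lrr = 0.789,
      u_dfs_chf = 0.670, u_met = 0.762
    ),
    costs = list(
      trast_drug = 787384650, her2_detection = 686116,
      trast_other_direct_medical = 27040970, trast_direct_nonmedical = 5724180,
      paclitaxel_treatment = 32116418,
      c_dfs = 1400846, c_lrr = 216688208, c_dfs_post_lrr = 1400846,
      c_met = 131065482, c_dfs_chf = 9529840,
      p_440 = 45596775, p_150 = 15550710,
      trast_drug_sharing = 570022437
    ),
    settings = list(
      start_age = 50, patient_weight = 52.9, cohort_size = 5052
    ),
    psa = list()
  )
  p <- .apply_param_defaults(p)
  class(p) <- "her2_params"
  validate_params(p)
  p
}

#' Load a model configuration file
#'
#' Reads a YAML configuration with sections `clinical`, `utilities`, `costs`,
#' `settings` and (optionally) `psa`, applies documented defaults to optional
#' fields, and validates the result. The bundled base case lives at
#' `system.file("extdata", "basecase.yaml", package = "her2cea")`.
#'
#' @param path path to a YAML configuration file.
#' @return a validated `her2_params` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("configuration must be a YAML mapping with named sections")
  unknown <- setdiff(names(raw), c("clinical", "utilities", "costs", "settings", "psa"))
  if (length(unknown)) stop("unknown configuration section(s): ", paste(unknown, collapse = ", "))
  if (!is.null(raw$settings$wtp_thresholds)) {
    raw$settings$wtp_thresholds <- as.numeric(unlist(raw$settings$wtp_thresholds))
  }
  p <- .apply_param_defaults(raw)
  class(p) <- "her2_params"
  validate_params(p)
  p
}

#' Save a parameter set to a configuration file
#'
#' Inverse of [load_config()]: round-tripping a valid parameter set through
#' `save_config()`/[load_config()] is lossless.
#'
#' @param p a `her2_params` list.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(p, path) {
  validate_params(p)
  yaml::write_yaml(unclass(p), path, precision = 15)
  invisible(path)
}

#' Fit a beta distribution by the method of moments
#'
#' Fits shape parameters so the distribution mean equals `mean` and the
#' standard deviation is `(hi - lo) / 3.92`, i.e. `(lo, hi)` is read as a
#' 95% interval. Used for transition probabilities and utilities.
#'
#' @param mean,lo,hi base value and interval bounds, all in `[0, 1]`.
#' @return named vector `c(alpha =, beta =)`.
#' @export
fit_beta <- function(mean, lo, hi) {
  if (!(lo <= mean && mean <= hi && lo < hi && lo >= 0 && hi <= 1)) {
    stop("fit_beta requires 0 <= lo <= mean <= hi <= 1 with lo < hi")
  }
  s2 <- ((hi - lo) / 3.92)^2
  if (s2 >= mean * (1 - mean)) {
    stop(sprintf("infeasible moments for beta: variance %.4g >= mean(1-mean) = %.4g",
                 s2, mean * (1 - mean)))
  }
  nu <- mean * (1 - mean) / s2 - 1
  c(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Fit a gamma distribution by the method of moments
#'
#' Mean equals `mean`, SD = `(hi - lo)/3.92`. Used for cost parameters.
#'
#' @param mean,lo,hi base value and 95% interval bounds, `0 < lo <= mean <= hi`.
#' @return named vector `c(shape =, scale =)`.
#' @export
fit_gamma <- function(mean, lo, hi) {
  if (!(is.numeric(mean) && mean > 0)) stop("fit_gamma requires a strictly positive mean")
  if (!(lo <= mean && mean <= hi && lo < hi && lo > 0)) {
    stop("fit_gamma requires 0 < lo <= mean <= hi with lo < hi")
  }
  s2 <- ((hi - lo) / 3.92)^2
  c(shape = mean^2 / s2, scale = s2 / mean)
}

#' Fit a log-normal distribution to a hazard ratio and its 95% CI
#'
#' `mu = log(hr)`, `sigma = (log(hi) - log(lo)) / 3.92`; the fitted median is
#' the base hazard ratio. A zero-width interval gives the degenerate
#' `sigma = 0`.
#'
#' @param hr,lo,hi hazard ratio and interval bounds, all strictly positive.
#' @return named vector `c(mu =, sigma =)`.
#' @export
fit_lognormal_hr <- function(hr, lo, hi) {
  if (!(lo > 0 && hr > 0 && hi > 0)) stop("fit_lognormal_hr requires strictly positive inputs")
  if (!(lo <= hr && hr <= hi)) stop("fit_lognormal_hr requires lo <= hr <= hi")
  c(mu = log(hr), sigma = (log(hi) - log(lo)) / 3.92)
}

# Uncertainty specification for every parameter sampled in the PSA / varied in
# the tornado. Probabilities and utilities: beta; relative effects: lognormal;
# costs: gamma. Ranges default to +/- rel_range (read as a 95% interval) except
# where a published CI is configured.
.psa_spec <- function(p) {
  m <- p$psa$rel_range
  rel <- function(x) c(lo = x * (1 - m), hi = x * (1 + m))
  relp <- function(x) c(lo = max(0, x * (1 - m)), hi = min(1, x * (1 + m)))
  spec <- list()
  for (nm in c("p_lrr_base", "p_met_base", "p_dfs_after_lrr", "p_chf_trast",
               "p_chf_chemo", "p_death_met", "p_lrr_chf", "p_met_chf")) {
    x <- p$clinical[[nm]]
    spec[[nm]] <- list(section = "clinical", family = "beta", base = x,
                       lo = relp(x)[["lo"]], hi = relp(x)[["hi"]])
  }
  for (nm in c("hr_lrr", "hr_met", "rr_met_after_lrr")) {
    x <- p$clinical[[nm]]
    ci <- p$psa[[paste0(nm, "_ci")]]
    if (is.null(ci)) ci <- rel(x)
    spec[[nm]] <- list(section = "clinical", family = "lognormal", base = x,
                       lo = ci[[1]], hi = ci[[2]])
  }
  for (nm in names(p$utilities)) {
    x <- p$utilities[[nm]]
    spec[[nm]] <- list(section = "utilities", family = "beta", base = x,
                       lo = relp(x)[["lo"]], hi = relp(x)[["hi"]])
  }
  for (nm in c("trast_drug", "her2_detection", "trast_other_direct_medical",
               "trast_direct_nonmedical", "paclitaxel_treatment",
               "c_dfs", "c_lrr", "c_dfs_post_lrr", "c_met", "c_dfs_chf")) {
    x <- p$costs[[nm]]
    if (x <= 0) next  # zero costs carry no gamma uncertainty
    spec[[nm]] <- list(section = "costs", family = "gamma", base = x,
                       lo = rel(x)[["lo"]], hi = rel(x)[["hi"]])
  }
  spec
}

#' Draw joint parameter samples for probabilistic sensitivity analysis
#'
#' Each of the `n` draws resamples every uncertain parameter independently
#' from its fitted distribution (beta for probabilities and utilities,
#' log-normal for relative treatment effects, gamma for costs); parameters
#' with a zero-width range are returned at their base value. Draws are
#' reproducible for a given `seed`.
#'
#' @param params a `her2_params` list.
#' @param n number of draws.
#' @param seed integer RNG seed.
#' @return data.frame with one row per draw and one column per sampled
#'   parameter, plus a `draw` index; the uncertainty specification used is attached as
#'   `attr(, "psa_spec")`.
#' @export
sample_psa <- function(params, n, seed) {
  validate_params(params)
  if (n < 1) stop("n must be >= 1")
  spec <- .psa_spec(params)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  out <- list(draw = seq_len(n))
  for (nm in names(spec)) {
    sp <- spec[[nm]]
    if (sp$hi - sp$lo <= 0) {
      out[[nm]] <- rep(sp$base, n)
      next
    }
    out[[nm]] <- switch(sp$family,
      beta = {
        ab <- fit_beta(sp$base, sp$lo, sp$hi)
        stats::rbeta(n, ab[["alpha"]], ab[["beta"]])
      },
      lognormal = {
        ms <- fit_lognormal_hr(sp$base, sp$lo, sp$hi)
        stats::rlnorm(n, ms[["mu"]], ms[["sigma"]])
      },
      gamma = {
        sh <- fit_gamma(sp$base, sp$lo, sp$hi)
        stats::rgamma(n, shape = sh[["shape"]], scale = sh[["scale"]])
      },
      stop("unknown family: ", sp$family)
    )
  }
  out <- as.data.frame(out)
  attr(out, "psa_spec") <- spec
  out
}

# Substitute one PSA draw (a named numeric row) into a parameter set.
.apply_draw <- function(params, draw) {
  spec <- .psa_spec(params)
  for (nm in names(draw)) {
    if (nm == "draw") next
    sec <- spec[[nm]]$section
    params[[sec]][[nm]] <- as.numeric(draw[[nm]])
  }
  params
}

#' Estimate the eligible treatment population
#'
#' Multiplies the national breast-cancer case count by the early-stage
#' fraction, the HER2+ fraction among early-stage cases, treatment coverage,
#' and the fraction passing the baseline cardiac assessment; rounds to the
#' nearest whole person.
#'
#' @param n_patients total breast cancer patients.
#' @param early_frac,her2_frac,coverage,cardiac_pass fractions in `[0, 1]`.
#' @return integer count.
#' @export
eligible_population <- function(n_patients, early_frac, her2_frac, coverage, cardiac_pass) {
  vals <- c(n_patients = n_patients, early_frac = early_frac, her2_frac = her2_frac,
            coverage = coverage, cardiac_pass = cardiac_pass)
  if (any(vals < 0)) stop("eligible_population inputs must be non-negative")
  fr <- vals[-1]
  if (any(fr > 1)) stop("fractions must lie in [0, 1]")
  round(n_patients * prod(fr))
}
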