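#' Gompertz-Makeham mortality law
#'
#' Annual hazard `a + c * exp(b * age)`; the implied annual death probability
#' is `qx = 1 - exp(-(a + c * exp(b * age)))`. Used to generate plausible
#' female background-mortality tables when the national life table is not at
#' hand.
#'
#' @param a background (age-independent) hazard per year.
#' @param b senescent slope per year of age.
#' @param c baseline senescent hazard per year.
#' @return a `mortality_law` list.
#' @export
mortality_law <- function(a = 5e-4, b = 0.11, c = 8e-6) {
  if (any(c(a, b, c) < 0)) stop("mortality law parameters must be non-negative")
  structure(list(family = "gompertz_makeham", a = a, b = b, c = c),
            class = "mortality_law")
}

#' Generate a life table from a mortality law
#'
#' Computes `qx` for each age from the hazard law and forces `qx = 1` at the
#' final age so the table closes out.
#'
#' @param law a [mortality_law()].
#' @param ages contiguous integer ages (default 0-100).
#' @return a `life_table`.
#' @export
make_lifetable <- function(law = mortality_law(), ages = 0:100) {
  if (!inherits(law, "mortality_law")) stop("'law' must be a mortality_law")
  if (any(diff(ages) != 1)) stop("'ages' must be contiguous")
  qx <- 1 - exp(-(law$a + law$c * exp(law$b * ages)))
  qx[length(qx)] <- 1
  life_table(ages, qx)
}

#' Approximate Vietnamese female life table (synthetic)
#'
#' A Gompertz-Makeham stand-in (`a = 5e-4`, `b = 0.11`, `c = 8e-6`, ages
#' 0-100) for the national 2020 female life table, giving a remaining life
#' expectancy at age 50 of roughly 31 years. It is an approximation for
#' offline use, not the published table; the same table ships as
#' `extdata/vietnam_2020_approx.tsv`.
#'
#' @return a `life_table`.
#' @export
vietnam_lifetable_approx <- function() {
  make_lifetable(mortality_law(a = 5e-4, b = 0.11, c = 8e-6), ages = 0:100)
}

#' Multiplicatively jitter a parameter set
#'
#' Robustness tool: every continuous parameter is multiplied by an independent
#' uniform factor in `[1 - magnitude, 1 + magnitude]`; probabilities and
#' utilities are clamped to `[0, 1]`. Settings are left untouched. The result
#' always passes [validate_params()].
#'
#' @param params a `her2_params` list.
#' @param magnitude relative jitter in `[0, 0.5]`.
#' @param seed integer RNG seed.
#' @return a jittered, validated `her2_params` list.
#' @export
jitter_params <- function(params, magnitude, seed) {
  validate_params(params)
  if (magnitude < 0 || magnitude > 0.5) stop("'magnitude' must lie in [0, 0.5]")
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  bounded <- c("p_lrr_base", "p_met_base", "p_dfs_after_lrr", "p_chf_trast",
               "p_chf_chemo", "p_death_met", "p_lrr_chf", "p_met_chf",
               names(params$utilities))
  for (sec in c("clinical", "utilities", "costs")) {
    for (nm in names(params[[sec]])) {
      f <- stats::runif(1, 1 - magnitude, 1 + magnitude)
      x <- params[[sec]][[nm]] * f
      if (nm %in% bounded) x <- min(1, max(0, x))
      params[[sec]][[nm]] <- x
    }
  }
  validate_params(params)
  params
}

#' A toy model with closed-form totals
#'
#' A single-live-state configuration: the cohort stays disease-free with a
#' constant annual death probability `p` (delivered through a flat life
#' table), utility `u`, annual state cost `cost`, discount rate `r`, and no
#' disease transitions or therapy one-offs. Discounted totals then have the
#' geometric closed form `sum_t ((1-p)/(1+r))^t x {1, u, cost}` over the
#' horizon, which anchors the cohort engine's accrual and discounting
#' conventions.
#'
#' @param p constant annual death probability.
#' @param u disease-free utility.
#' @param cost annual disease-free state cost.
#' @param r discount rate per year.
#' @param horizon number of annual cycles.
#' @return list with elements `params`, `lifetable`, and `expected`
#'   (`cost`, `ly`, `qaly` closed-form discounted totals per person).
#' @export
make_toy_model <- function(p = 0.5, u = 1, cost = 0, r = 0, horizon = 50) {
  prm <- default_params()
  prm$clinical[c("p_lrr_base", "p_met_base", "p_dfs_after_lrr",
                 "p_chf_trast", "p_chf_chemo", "p_lrr_chf", "p_met_chf")] <-
    rep(list(0), 7)
  prm$clinical$p_death_met <- 0
  prm$utilities[] <- rep(list(u), length(prm$utilities))
  prm$costs[] <- rep(list(0), length(prm$costs))
  prm$costs$c_dfs <- cost
  prm$settings$discount_rate <- r
  prm$settings$start_age <- 0
  prm$settings$max_age <- horizon
  prm$settings$recurrence_cutoff <- min(20, horizon)
  prm$settings$benefit_duration <- min(5, prm$settings$recurrence_cutoff)
  validate_params(prm)
  lt <- life_table(0:horizon, c(rep(p, horizon), 1))
  t <- 0:(horizon - 1)
  w <- ((1 - p) / (1 + r))^t
  # at the final cycle the table forces qx = 1, so accrual stops after
  # `horizon` start-of-cycle rewards
  list(params = prm, lifetable = lt,
       expected = list(ly = sum(w), qaly = u * sum(w), cost = cost * sum(w)))
}
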