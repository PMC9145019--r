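# Interaction kinetics: competitive inhibition, mechanism-based
# inactivation, induction, and the enzyme turnover pool they act on.
# All driving concentrations are unbound concentrations in the organ where
# the enzyme resides.

#' Construct an interaction parameter block
#'
#' @param perpetrator perpetrator compound name
#' @param enzyme target enzyme identifier
#' @param mechanism `"competitive"`, `"mechanism_based"` or `"induction"`
#' @param ki_umol_L competitive inhibition constant (umol/L, unbound)
#' @param kinact_per_h maximal inactivation rate (1/h)
#' @param KI_umol_L half-maximal inactivation concentration (umol/L, unbound)
#' @param emax maximal fold induction of synthesis minus one (dimensionless)
#' @param ec50_umol_L half-maximal induction concentration (umol/L, unbound)
#' @return an `interaction_parameters`
#' @export
interaction_parameters <- function(perpetrator, enzyme,
                                   mechanism = c("competitive",
                                                 "mechanism_based",
                                                 "induction"),
                                   ki_umol_L = NA_real_,
                                   kinact_per_h = NA_real_,
                                   KI_umol_L = NA_real_,
                                   emax = NA_real_, ec50_umol_L = NA_real_) {
  mechanism <- match.arg(mechanism)
  need <- switch(mechanism,
    competitive = c(ki_umol_L = ki_umol_L),
    mechanism_based = c(kinact_per_h = kinact_per_h, KI_umol_L = KI_umol_L),
    induction = c(emax = emax, ec50_umol_L = ec50_umol_L))
  bad <- names(need)[!is.finite(need) | need <= 0]
  assert_that(length(bad) == 0,
              sprintf("%s on %s (%s): parameters %s must be positive",
                      perpetrator, enzyme, mechanism,
                      paste(bad, collapse = ", ")))
  structure(list(perpetrator = perpetrator, enzyme = enzyme,
                 mechanism = mechanism, ki_umol_L = ki_umol_L,
                 kinact_per_h = kinact_per_h, KI_umol_L = KI_umol_L,
                 emax = emax, ec50_umol_L = ec50_umol_L),
            class = "interaction_parameters")
}

#' Competitive inhibition multiplier on apparent K_M
#'
#' Rate law under competitive inhibition:
#' `v = kcat * E * C / (K_M * (1 + I/K_i) + C)`; this helper returns the
#' factor `1 + I/K_i`.
#'
#' @param inhibitor_conc unbound inhibitor concentration (umol/L, >= 0)
#' @param ki_umol_L inhibition constant (umol/L, > 0)
#' @return dimensionless multiplier >= 1
#' @export
competitive_km_multiplier <- function(inhibitor_conc, ki_umol_L) {
  assert_that(all(inhibitor_conc >= 0), "inhibitor concentration must be >= 0")
  assert_that(all(ki_umol_L > 0), "K_i must be > 0")
  1 + inhibitor_conc / ki_umol_L
}

#' Mechanism-based inactivation rate of active enzyme
#'
#' First-order loss rate `kinact * I / (K_I + I)` (1/h), saturating at
#' `kinact` for large inhibitor concentrations.
#'
#' @param inhibitor_conc unbound inhibitor concentration (umol/L, >= 0)
#' @param kinact_per_h maximal inactivation rate (1/h, >= 0)
#' @param KI_umol_L half-maximal concentration (umol/L, > 0)
#' @return inactivation rate in 1/h
#' @export
inactivation_rate <- function(inhibitor_conc, kinact_per_h, KI_umol_L) {
  assert_that(all(inhibitor_conc >= 0) && all(kinact_per_h >= 0),
              "inactivation inputs must be nonnegative")
  assert_that(all(KI_umol_L > 0), "K_I must be > 0")
  kinact_per_h * inhibitor_conc / (KI_umol_L + inhibitor_conc)
}

#' Induction multiplier on enzyme synthesis
#'
#' `1 + E_max * I / (EC_50 + I)`, i.e. baseline synthesis at I = 0 and
#' (1 + E_max)-fold synthesis at saturating inducer concentration.
#'
#' @param inducer_conc unbound inducer concentration (umol/L, >= 0)
#' @param emax maximal induction effect (dimensionless, >= 0)
#' @param ec50_umol_L half-maximal concentration (umol/L, > 0)
#' @return dimensionless multiplier >= 1
#' @export
induction_multiplier <- function(inducer_conc, emax, ec50_umol_L) {
  assert_that(all(inducer_conc >= 0) && all(emax >= 0),
              "induction inputs must be nonnegative")
  assert_that(all(ec50_umol_L > 0), "EC_50 must be > 0")
  1 + emax * inducer_conc / (ec50_umol_L + inducer_conc)
}

#' Construct an enzyme pool state
#'
#' Relative active enzyme with first-order turnover: baseline synthesis is
#' implied as `kdeg * 1.0` so the interaction-free steady state is 1.
#'
#' @param enzyme enzyme identifier
#' @param organ organ identifier
#' @param amount relative active enzyme (>= 0; 1 = baseline)
#' @param kdeg_per_h first-order turnover rate (1/h, > 0)
#' @return an `enzyme_pool_state`
#' @export
enzyme_pool_state <- function(enzyme, organ, amount = 1, kdeg_per_h) {
  assert_that(amount >= 0, "enzyme amount must be >= 0")
  assert_that(kdeg_per_h > 0, "kdeg must be > 0")
  structure(list(enzyme = enzyme, organ = organ, amount = amount,
                 kdeg_per_h = kdeg_per_h),
            class = "enzyme_pool_state")
}

#' Time derivative of the active enzyme pool
#'
#' `d(amount)/dt = kdeg * m_ind - kdeg * amount - lambda * amount` where
#' `m_ind` is the induction multiplier on synthesis and `lambda` the
#' mechanism-based inactivation rate. At baseline (amount 1, no perpetrator)
#' the derivative is zero; under constant perpetrator exposure the pool
#' relaxes to `kdeg * m_ind / (kdeg + lambda)`.
#'
#' @param state an [enzyme_pool_state()]
#' @param inactivation_rate first-order inactivation rate (1/h)
#' @param induction_multiplier synthesis multiplier (dimensionless)
#' @return d(amount)/dt in 1/h
#' @export
enzyme_pool_derivative <- function(state, inactivation_rate = 0,
                                   induction_multiplier = 1) {
  assert_that(inherits(state, "enzyme_pool_state"), "not an enzyme_pool_state")
  state$kdeg_per_h * induction_multiplier -
    state$kdeg_per_h * state$amount - inactivation_rate * state$amount
}
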