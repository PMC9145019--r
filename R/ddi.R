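# Drug-gene and drug-drug interaction scenarios: simplified partner-drug
# stubs (linear, enzyme-mediated disposition on the shared physiological
# scaffold) coupled with the clopidogrel network in one ODE system.

#' Construct a partner-drug stub
#'
#' Partner drugs are deliberately simplified: first-order absorption,
#' scalar partitioning, linear enzyme-mediated hepatic elimination (scaled
#' by the enzyme's active pool, hence responsive to inactivation, induction
#' and competitive inhibition) plus an optional nonspecific clearance.
#' Perpetrators additionally carry interaction parameter blocks.
#'
#' @param name partner name
#' @param mw_g_mol molecular weight (g/mol)
#' @param fu fraction unbound
#' @param kp scalar tissue partition coefficient
#' @param ka_per_h absorption rate (1/h)
#' @param enzyme_cl named list/vector: enzyme -> unbound-referenced hepatic
#'   clearance (L/h) mediated by that enzyme
#' @param cl_nonspecific_L_per_h nonspecific hepatic clearance (L/h)
#' @param metabolite_of optional named product: enzyme -> product compound
#'   name (the product must be added to the model as its own stub)
#' @param role `"victim"`, `"perpetrator"` or `"both"`
#' @param interactions list of [interaction_parameters()] with this stub as
#'   perpetrator
#' @return a `partner_stub`
#' @export
partner_stub <- function(name, mw_g_mol, fu, kp, ka_per_h = 0,
                         enzyme_cl = list(), cl_nonspecific_L_per_h = 0,
                         metabolite_of = list(),
                         role = c("victim", "perpetrator", "both"),
                         interactions = list()) {
  role <- match.arg(role)
  if (role %in% c("victim", "both"))
    assert_that(length(enzyme_cl) > 0,
                sprintf("victim stub '%s' must declare enzyme-mediated elimination", name))
  if (role %in% c("perpetrator", "both"))
    assert_that(length(interactions) > 0,
                sprintf("perpetrator stub '%s' must declare interaction parameters", name))
  structure(list(name = name, mw_g_mol = mw_g_mol, fu = fu, kp = kp,
                 ka_per_h = ka_per_h, enzyme_cl = enzyme_cl,
                 cl_nonspecific_L_per_h = cl_nonspecific_L_per_h,
                 metabolite_of = metabolite_of, role = role,
                 interactions = interactions),
            class = "partner_stub")
}

#' Built-in partner-drug stubs of the clopidogrel interaction network
#'
#' Bupropion (CYP2B6 victim, hydroxybupropion readout), omeprazole (CYP2C19
#' victim and mechanism-based CYP2C19 inactivator), montelukast,
#' pioglitazone and repaglinide (CYP2C8 victims), and rifampicin (CYP2C19
#' inducer, CYP3A4 inducer and competitive inhibitor). Disposition
#' parameters are package defaults chosen to give plausible exposure
#' kinetics; the interaction machinery, not the partner exposures, is the
#' tested surface.
#'
#' @return named list of [partner_stub()]s
#' @export
builtin_partners <- function() {
  list(
    bupropion = partner_stub(
      "bupropion", 239.74, fu = 0.16, kp = 8, ka_per_h = 1.5,
      enzyme_cl = list(CYP2B6 = 450),
      cl_nonspecific_L_per_h = 150,
      metabolite_of = list(CYP2B6 = "hydroxybupropion"),
      role = "victim"),
    hydroxybupropion = partner_stub(
      "hydroxybupropion", 255.74, fu = 0.23, kp = 3, ka_per_h = 0,
      enzyme_cl = list(CYP2B6 = 1e-6),  # formally enzyme-linked, negligible
      cl_nonspecific_L_per_h = 30,
      role = "victim"),
    omeprazole = partner_stub(
      "omeprazole", 345.42, fu = 0.03, kp = 2, ka_per_h = 3,
      enzyme_cl = list(CYP2C19 = 4000, CYP3A4 = 1500),
      role = "both",
      interactions = list(interaction_parameters(
        "omeprazole", "CYP2C19", "mechanism_based",
        kinact_per_h = 2.6, KI_umol_L = 1.2))),
    montelukast = partner_stub(
      "montelukast", 586.18, fu = 0.001, kp = 5, ka_per_h = 1,
      enzyme_cl = list(CYP2C8 = 30000, CYP3A4 = 8000),
      role = "victim"),
    pioglitazone = partner_stub(
      "pioglitazone", 356.44, fu = 0.01, kp = 3, ka_per_h = 2,
      enzyme_cl = list(CYP2C8 = 8000, CYP3A4 = 2000),
      role = "victim"),
    repaglinide = partner_stub(
      "repaglinide", 452.59, fu = 0.015, kp = 2, ka_per_h = 2.5,
      enzyme_cl = list(CYP2C8 = 20000, CYP3A4 = 6000),
      cl_nonspecific_L_per_h = 1000,
      role = "victim"),
    rifampicin = partner_stub(
      "rifampicin", 822.94, fu = 0.17, kp = 1, ka_per_h = 1.2,
      cl_nonspecific_L_per_h = 40,
      role = "perpetrator",
      interactions = list(
        interaction_parameters("rifampicin", "CYP3A4", "induction",
                               emax = 9, ec50_umol_L = 0.34),
        interaction_parameters("rifampicin", "CYP2C19", "induction",
                               emax = 2.5, ec50_umol_L = 0.34),
        interaction_parameters("rifampicin", "CYP3A4", "competitive",
                               ki_umol_L = 18.5)))
  )
}

#' Couple a partner stub into a model definition
#'
#' @param model a `model_definition`
#' @param partner a [partner_stub()]
#' @return extended `model_definition`
#' @export
add_partner_to_model <- function(model, partner) {
  assert_that(inherits(partner, "partner_stub"), "not a partner_stub")
  assert_that(!partner$name %in% names(model$compounds),
              sprintf("compound '%s' already in the model", partner$name))
  cp <- compound(partner$name, partner$mw_g_mol, fu = partner$fu,
                 kp = partner$kp, ka_per_h = partner$ka_per_h)
  compounds <- c(model$compounds, setNames(list(cp), partner$name))
  clearances <- model$clearances
  for (enz in names(partner$enzyme_cl)) {
    prod <- partner$metabolite_of[[enz]] %||% NA_character_
    clearances[[length(clearances) + 1]] <- clearance_process(
      partner$name, "hepatic", partner$enzyme_cl[[enz]],
      enzyme = enz, product = prod, fittable = FALSE)
  }
  if (partner$cl_nonspecific_L_per_h > 0)
    clearances[[length(clearances) + 1]] <- clearance_process(
      partner$name, "hepatic", partner$cl_nonspecific_L_per_h,
      fittable = FALSE)
  model_definition(compounds, model$processes, clearances,
                   c(model$interactions, partner$interactions))
}

#' Construct a DDI scenario definition
#'
#' The control arm differs from the DDI arm only by absence of the
#' perpetrator regimen.
#'
#' @param victim_regimen [regimen()] of the victim drug
#' @param perpetrator_regimen [regimen()] of the perpetrator drug
#' @param readout_compound compound whose exposure is the readout
#' @param readout_window numeric c(t_first, t_last) in h (default: full
#'   simulation window)
#' @param phenotype CYP2C19 phenotype of the virtual individual
#' @param t_end_h simulation end time
#' @return a `scenario_definition`
#' @export
scenario_definition <- function(victim_regimen, perpetrator_regimen,
                                readout_compound,
                                readout_window = NULL, phenotype = "NM",
                                t_end_h = NULL) {
  structure(list(victim_regimen = victim_regimen,
                 perpetrator_regimen = perpetrator_regimen,
                 readout_compound = readout_compound,
                 readout_window = readout_window, phenotype = phenotype,
                 t_end_h = t_end_h),
            class = "scenario_definition")
}

scenario_metrics <- function(sim, compound, window = NULL) {
  pr <- plasma_profile(sim, compound)
  w <- window %||% range(pr$time_h)
  pk_metrics(pr$time_h, pr$conc_ng_ml, w[1], w[2])
}

#' Run a CYP2C19 drug-gene interaction scenario
#'
#' Simulates the identical regimen under the NM reference phenotype and
#' under the requested phenotype, and returns AUC_last and C_max ratios
#' (phenotype over NM) for the readout compound.
#'
#' @param model a `model_definition` (clopidogrel network)
#' @param individual an `individual`
#' @param regimen a [regimen()]
#' @param phenotype `"IM"` or `"PM"` (NM gives the degenerate ratio 1)
#' @param readout_compound readout (default `"Clo-AM"`)
#' @param observed_ratios optional named vector
#'   `c(AUC_last = ..., C_max = ...)` of observed ratios for Guest bounds
#' @param settings [solver_settings()]
#' @return a `dgi_result`: list of two [ratio_result()]s plus the two PK
#'   metric sets
#' @export
run_dgi_scenario <- function(model, individual, regimen, phenotype,
                             readout_compound = "Clo-AM",
                             observed_ratios = NULL,
                             settings = solver_settings()) {
  assert_that(phenotype %in% names(CYP2C19_ACTIVITY),
              sprintf("unknown phenotype '%s'", phenotype))
  sim_ref <- simulate_pbpk(model, set_phenotype(individual, "NM"), regimen,
                           settings)
  sim_dgi <- simulate_pbpk(model, set_phenotype(individual, phenotype),
                           regimen, settings)
  pk_ref <- scenario_metrics(sim_ref, readout_compound)
  pk_dgi <- scenario_metrics(sim_dgi, readout_compound)
  obs <- observed_ratios %||% c(AUC_last = NA_real_, C_max = NA_real_)
  structure(list(
    phenotype = phenotype, readout = readout_compound,
    auc = ratio_result("DGI", "AUC_last",
                       interaction_ratio(pk_dgi$AUC_last, pk_ref$AUC_last),
                       obs[["AUC_last"]]),
    cmax = ratio_result("DGI", "C_max",
                        interaction_ratio(pk_dgi$C_max, pk_ref$C_max),
                        obs[["C_max"]]),
    pk_reference = pk_ref, pk_interaction = pk_dgi
  ), class = "dgi_result")
}

#' Run a drug-drug interaction scenario
#'
#' Couples victim and perpetrator in one ODE system (the only coupling is
#' through interaction kinetics on shared enzymes), simulates control and
#' DDI arms, and returns AUC_last and C_max ratios for the readout.
#'
#' @param model base `model_definition` (without the partner, unless the
#'   partner is already a model compound)
#' @param partner a [partner_stub()] or `NULL` when both drugs are already
#'   in `model`
#' @param scenario a [scenario_definition()]
#' @param individual an `individual`
#' @param observed_ratios optional named vector
#'   `c(AUC_last = ..., C_max = ...)`
#' @param settings [solver_settings()]
#' @return a `ddi_result`: two [ratio_result()]s plus both arms' PK metrics
#' @export
run_ddi_scenario <- function(model, partner, scenario,
                             individual = build_reference_individual(),
                             observed_ratios = NULL,
                             settings = solver_settings()) {
  assert_that(inherits(scenario, "scenario_definition"),
              "not a scenario_definition")
  full <- model
  if (!is.null(partner)) full <- add_partner_to_model(full, partner)
  ind <- set_phenotype(individual, scenario$phenotype)

  # sanity: does any interaction touch an enzyme that eliminates the readout?
  victim_enzymes <- unique(c(
    vapply(full$processes, function(p)
      if (identical(p$substrate, scenario$readout_compound) ||
          identical(p$product, scenario$readout_compound)) p$enzyme
      else NA_character_, character(1)),
    vapply(full$clearances, function(cl)
      if (identical(cl$compound, scenario$readout_compound)) cl$enzyme
      else NA_character_, character(1))))
  ia_enzymes <- vapply(full$interactions, `[[`, character(1), "enzyme")
  if (length(ia_enzymes) && !any(ia_enzymes %in% victim_enzymes))
    warning("no interaction targets an enzyme involved in the readout's ",
            "disposition; expecting a null ratio", call. = FALSE)

  ev_all <- c(scenario$victim_regimen$events,
              scenario$perpetrator_regimen$events)
  t_end <- scenario$t_end_h %||%
    (max(vapply(ev_all, `[[`, numeric(1), "time_h")) + 24)
  st <- settings
  st$t_end <- t_end

  sim_ctrl <- simulate_pbpk(full, ind, scenario$victim_regimen, st)
  sim_ddi <- simulate_pbpk(full, ind, regimen(ev_all, "DDI arm"), st)
  pk_ctrl <- scenario_metrics(sim_ctrl, scenario$readout_compound,
                              scenario$readout_window)
  pk_ddi <- scenario_metrics(sim_ddi, scenario$readout_compound,
                             scenario$readout_window)
  obs <- observed_ratios %||% c(AUC_last = NA_real_, C_max = NA_real_)
  structure(list(
    readout = scenario$readout_compound,
    auc = ratio_result("DDI", "AUC_last",
                       interaction_ratio(pk_ddi$AUC_last, pk_ctrl$AUC_last),
                       obs[["AUC_last"]]),
    cmax = ratio_result("DDI", "C_max",
                        interaction_ratio(pk_ddi$C_max, pk_ctrl$C_max),
                        obs[["C_max"]]),
    pk_control = pk_ctrl, pk_ddi = pk_ddi
  ), class = "ddi_result")
}

#' @export
print.dgi_result <- function(x, ...) {
  cat("<dgi_result>", x$phenotype, "vs NM, readout", x$readout, "\n")
  print(x$auc); print(x$cmax)
  invisible(x)
}

#' @export
print.ddi_result <- function(x, ...) {
  cat("<ddi_result> readout", x$readout, "\n")
  print(x$auc); print(x$cmax)
  invisible(x)
}
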