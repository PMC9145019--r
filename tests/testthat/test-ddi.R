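clo_md <- regimen(lapply(0:4, function(i)
  dose_event("clopidogrel", "po", 75, i * 24)), "clopidogrel 75 mg MD")

test_that("DGI ratios are 1 for the degenerate NM case and monotone in activity", {
  mod <- the_model()
  ind <- the_individual()
  reg <- dosing_regimen(300, route = "po")
  st <- solver_settings(t_end = 24, dt = 0.25)

  nm <- run_dgi_scenario(mod, ind, reg, "NM", settings = st)
  expect_equal(nm$auc$predicted_ratio, 1)
  expect_equal(nm$cmax$predicted_ratio, 1)

  im <- run_dgi_scenario(mod, ind, reg, "IM", settings = st)
  pm <- run_dgi_scenario(mod, ind, reg, "PM", settings = st)
  # impaired activation: less active metabolite in poor metabolizers
  expect_lt(pm$auc$predicted_ratio, 1)
  expect_lt(pm$cmax$predicted_ratio, 1)
  expect_true(pm$auc$predicted_ratio < im$auc$predicted_ratio &&
                im$auc$predicted_ratio < 1)
  expect_error(run_dgi_scenario(mod, ind, reg, "XX"), "phenotype")
})

test_that("a dosed partner with no interaction parameters leaves ratios at 1", {
  # montelukast has no perpetrator block; co-dosing it with the victim must
  # not move the victim at all (the only inter-drug coupling is interaction
  # kinetics); agreement is to solver precision
  mod <- the_model()
  mod$interactions <- list()  # also strip autoinhibition edges
  monte <- builtin_partners()$montelukast
  sc <- scenario_definition(
    dosing_regimen(75, route = "po"),
    regimen(list(dose_event("montelukast", "po", 10)), "monte"),
    readout_compound = "clopidogrel", t_end_h = 24)
  res <- run_ddi_scenario(mod, monte, sc, the_individual(),
                          settings = solver_settings(dt = 0.25))
  expect_equal(res$auc$predicted_ratio, 1, tolerance = 1e-6)
  expect_equal(res$cmax$predicted_ratio, 1, tolerance = 1e-6)
})

test_that("a victim not metabolized by the targeted enzyme is unaffected", {
  # keep only the CYP2B6 autoinhibition edge; montelukast (CYP2C8/CYP3A4)
  # carries no CYP2B6-mediated elimination, so the ratio must be null and a
  # warning is raised
  mod <- the_model()
  mod$interactions <- Filter(function(ia) ia$enzyme == "CYP2B6",
                             mod$interactions)
  monte_reg <- regimen(list(dose_event("montelukast", "po", 10, 96)),
                       "monte")
  sc <- scenario_definition(monte_reg, clo_md, "montelukast",
                            readout_window = c(96, 120))
  expect_warning(
    res <- run_ddi_scenario(mod, builtin_partners()$montelukast, sc,
                            the_individual(),
                            settings = solver_settings(dt = 0.25)),
    "null ratio")
  expect_equal(res$auc$predicted_ratio, 1, tolerance = 1e-6)
})

test_that("omeprazole co-treatment decreases and rifampicin pretreatment increases Clo-AM", {
  mod <- the_model()
  ind <- the_individual()
  partners <- builtin_partners()
  st <- solver_settings(dt = 0.25)

  omep_md <- regimen(lapply(0:4, function(i)
    dose_event("omeprazole", "po", 80, i * 24)), "omeprazole MD")
  sc1 <- scenario_definition(clo_md, omep_md, "Clo-AM",
                             readout_window = c(96, 120))
  r1 <- run_ddi_scenario(mod, partners$omeprazole, sc1, ind, settings = st)
  expect_lt(r1$auc$predicted_ratio, 0.95)

  clo_sd <- regimen(list(dose_event("clopidogrel", "po", 300, 168)),
                    "clopidogrel after rifampicin")
  rif_md <- regimen(lapply(0:6, function(i)
    dose_event("rifampicin", "po", 600, i * 24)), "rifampicin MD")
  sc2 <- scenario_definition(clo_sd, rif_md, "Clo-AM",
                             readout_window = c(168, 192))
  r2 <- run_ddi_scenario(mod, partners$rifampicin, sc2, ind, settings = st)
  expect_gt(r2$auc$predicted_ratio, 1.2)
})

test_that("clopidogrel pretreatment raises CYP2C8-substrate and lowers hydroxybupropion exposure", {
  mod <- the_model()
  ind <- the_individual()
  partners <- builtin_partners()
  st <- solver_settings(dt = 0.25)

  repa <- regimen(list(dose_event("repaglinide", "po", 0.25, 96)), "repa")
  sc <- scenario_definition(repa, clo_md, "repaglinide",
                            readout_window = c(96, 120))
  r <- run_ddi_scenario(mod, partners$repaglinide, sc, ind, settings = st)
  expect_gt(r$auc$predicted_ratio, 1.2)

  bup_model <- add_partner_to_model(mod, partners$bupropion)
  bup <- regimen(list(dose_event("bupropion", "po", 150, 96)), "bupropion")
  sc2 <- scenario_definition(bup, clo_md, "hydroxybupropion",
                             readout_window = c(96, 120))
  r2 <- run_ddi_scenario(bup_model, partners$hydroxybupropion, sc2, ind,
                         settings = st)
  expect_lt(r2$auc$predicted_ratio, 0.95)
})

test_that("mechanism-based effects persist after washout; competitive effects do not", {
  # perpetrator dosed on days 0-2, victim (omeprazole as CYP2C19 probe)
  # dosed 48 h after the last perpetrator dose
  ind <- the_individual()
  base <- zero_rate_model()
  base$interactions <- list()
  omep <- builtin_partners()$omeprazole  # CYP2C19-eliminated victim probe
  omep$interactions <- list()
  omep$role <- "victim"
  victim <- regimen(list(dose_event("omeprazole", "po", 20, 96)), "probe")
  st <- solver_settings(dt = 0.25)

  mk_perp <- function(ia) partner_stub(
    "perp", 400, fu = 0.1, kp = 1, ka_per_h = 2,
    enzyme_cl = list(CYP3A4 = 1e-6), cl_nonspecific_L_per_h = 200,
    role = "both", interactions = list(ia))
  perp_md <- regimen(lapply(0:2, function(i)
    dose_event("perp", "po", 100, i * 24)), "perp MD")

  mbi <- mk_perp(interaction_parameters("perp", "CYP2C19",
                                        "mechanism_based",
                                        kinact_per_h = 3, KI_umol_L = 0.05))
  comp <- mk_perp(interaction_parameters("perp", "CYP2C19", "competitive",
                                         ki_umol_L = 0.05))
  run_one <- function(p) {
    m <- add_partner_to_model(add_partner_to_model(base, omep), p)
    sc <- scenario_definition(victim, perp_md, "omeprazole",
                              readout_window = c(96, 120))
    run_ddi_scenario(m, NULL, sc, ind, settings = st)$auc$predicted_ratio
  }
  ratio_mbi <- run_one(mbi)
  ratio_comp <- run_one(comp)
  expect_gt(ratio_mbi, 1.3)             # enzyme pool still depleted
  expect_lt(abs(ratio_comp - 1), 0.02)  # perpetrator already eliminated
})
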