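test_that("zero dose gives identically zero concentrations", {
  reg <- regimen(list(dose_event("clopidogrel", "po", 0)), "null")
  sim <- simulate_pbpk(the_model(), the_individual(), reg,
                       solver_settings(times = seq(0, 6, by = 1)))
  expect_true(all(sim$conc == 0))
  expect_true(all(sim$amounts == 0))
})

test_that("with all rates zeroed an iv bolus is conserved exactly", {
  mod <- zero_rate_model()
  reg <- dosing_regimen(50, route = "iv")
  sim <- simulate_pbpk(mod, the_individual(), reg,
                       solver_settings(times = seq(0, 48, by = 2)))
  dose_umol <- 50 * 1000 / mod$compounds$clopidogrel$mw_g_mol
  ci <- match("clopidogrel", sim$compounds)
  total <- rowSums(sim$amounts[, (ci - 1) * 7 + seq_len(7)])
  expect_equal(total, rep(dose_umol, length(sim$times)), tolerance = 1e-8)
})

test_that("low-extraction linear model matches the closed-form AUC within 1%", {
  # renal extraction ratio ~0.3%, so plasma clearance ~= CL_u * fu and
  # AUC(0->inf) ~= Dose / (CL_u * fu); fine early grid resolves the brief
  # distribution phase of the iv bolus for the trapezoid
  mod <- one_compartment_model(cl_unbound_L_per_h = 20, fu = 0.01, kp = 0.02)
  dose_mg <- 10
  tt <- sort(unique(c(seq(0, 2, by = 0.01), seq(2, 300, by = 0.25))))
  sim <- simulate_pbpk(mod, the_individual(),
                       regimen(list(dose_event("testdrug", "iv", dose_mg))),
                       solver_settings(times = tt))
  umol_per_ml_to_ng <- mod$compounds$testdrug$mw_g_mol
  auc <- trapz(sim$times, sim$conc[, 1]) / umol_per_ml_to_ng  # umol*h/L
  expect_equal(auc, (dose_mg * 1000 / umol_per_ml_to_ng) / (20 * 0.01),
               tolerance = 0.01)
})

test_that("mass balance holds on oral and intravenous simulations", {
  for (route in c("po", "iv")) {
    sim <- simulate_pbpk(the_model(), the_individual(),
                         dosing_regimen(300, route = route),
                         solver_settings(t_end = 48))
    mb <- mass_balance_report(sim)
    expect_lt(abs(mb$balance_rel_error), 1e-6)
  }
})

test_that("oral first-pass produces a much lower parent exposure than iv", {
  st <- solver_settings(t_end = 48)
  po <- simulate_pbpk(the_model(), the_individual(),
                      dosing_regimen(75, route = "po"), st)
  iv <- simulate_pbpk(the_model(), the_individual(),
                      dosing_regimen(75, route = "iv"), st)
  auc_po <- trapz(po$times, po$conc[, "clopidogrel"])
  auc_iv <- trapz(iv$times, iv$conc[, "clopidogrel"])
  expect_gt(auc_iv / auc_po, 10)
})

test_that("AUC scales linearly with dose in the sub-saturating limit", {
  st <- solver_settings(t_end = 48)
  auc <- vapply(c(1, 5), function(d) {
    sim <- simulate_pbpk(the_model(), the_individual(),
                         dosing_regimen(d, route = "po"), st)
    vapply(sim$compounds, function(cp) trapz(sim$times, sim$conc[, cp]),
           numeric(1))
  }, numeric(5))
  expect_equal(unname(auc[, 2] / auc[, 1]), rep(5, 5), tolerance = 0.02)
})

test_that("refining solver tolerance changes AUC by < 0.1%", {
  reg <- dosing_regimen(75, route = "po")
  coarse <- simulate_pbpk(the_model(), the_individual(), reg,
                          solver_settings(t_end = 24, rtol = 1e-6,
                                          atol = 1e-8))
  fine <- simulate_pbpk(the_model(), the_individual(), reg,
                        solver_settings(t_end = 24, rtol = 1e-7,
                                        atol = 1e-9))
  for (cp in coarse$compounds) {
    a1 <- trapz(coarse$times, coarse$conc[, cp])
    a2 <- trapz(fine$times, fine$conc[, cp])
    expect_equal(a1, a2, tolerance = 1e-3)
  }
})

test_that("phenotype acts exclusively through CYP2C19 catalytic rates", {
  st <- solver_settings(t_end = 24)
  reg <- dosing_regimen(75, route = "po")
  mod <- the_model()
  mod$interactions <- list()  # isolate phenotype effect from autoinhibition
  nm <- simulate_pbpk(mod, set_phenotype(the_individual(), "NM"), reg, st)
  pm <- simulate_pbpk(mod, set_phenotype(the_individual(), "PM"), reg, st)
  fl_nm <- process_fluxes(nm)
  fl_pm <- process_fluxes(pm)
  cyp2c19 <- grepl("\\|CYP2C19\\|", names(fl_nm))
  expect_true(all(fl_pm[cyp2c19] == 0))
  expect_true(all(fl_nm[cyp2c19] > 0))
  # with CYP2C19 catalytically silent, the phenotype switch touches nothing:
  # the whole state trajectory is bitwise identical across phenotypes
  silent <- mod
  for (i in seq_along(silent$processes))
    if (silent$processes[[i]]$enzyme == "CYP2C19")
      silent$processes[[i]]$kcat_per_min <- 0
  s_nm <- simulate_pbpk(silent, set_phenotype(the_individual(), "NM"), reg, st)
  s_pm <- simulate_pbpk(silent, set_phenotype(the_individual(), "PM"), reg, st)
  expect_identical(s_nm$y, s_pm$y)
})

test_that("daily dosing reaches a periodic steady state for Clo-COOH troughs", {
  sim <- simulate_pbpk(the_model(), the_individual(),
                       dosing_regimen(75, route = "po", n = 10),
                       solver_settings(t_end = 240, dt = 0.5))
  troughs <- sim$conc[match(c(192, 216, 240), sim$times), "Clo-COOH"]
  expect_equal(troughs[2] / troughs[1], troughs[3] / troughs[2],
               tolerance = 0.01)
  expect_equal(troughs[3] / troughs[2], 1, tolerance = 0.02)
})

test_that("pk_metrics implements the trapezoid/window contract", {
  m <- pk_metrics(c(0, 1, 2), c(0, 10, 5))
  expect_equal(m$AUC_last, 12.5)
  expect_equal(m$C_max, 10)
  expect_equal(m$t_max, 1)

  single <- pk_metrics(5, 42)
  expect_equal(single$AUC_last, 0)
  expect_equal(single$C_max, 42)

  tt <- seq(0, 12, by = 0.01)
  m2 <- pk_metrics(tt, 100 * exp(-0.5 * tt))
  expect_equal(m2$AUC_last, (100 / 0.5) * (1 - exp(-0.5 * 12)),
               tolerance = 0.005)

  expect_error(pk_metrics(c(0, 1), c(1, 2), t_first = 5, t_last = 6),
               "empty")
})

test_that("simulation output round-trips to a tidy table", {
  sim <- simulate_pbpk(the_model(), the_individual(),
                       dosing_regimen(75, route = "po"),
                       solver_settings(times = c(0, 1, 2)))
  df <- as.data.frame(sim)
  expect_named(df, c("time_h", "compound", "compartment", "amount_umol",
                     "plasma_conc_ng_ml"))
  expect_equal(nrow(df), 3 * 5 * 7)
  pp <- plasma_profile(sim, "Clo-COOH")
  expect_equal(pp$conc_ng_ml,
               df$plasma_conc_ng_ml[df$compound == "Clo-COOH" &
                                    df$compartment == "venous_blood"])
})
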