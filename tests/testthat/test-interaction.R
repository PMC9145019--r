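test_that("interaction multipliers reproduce their limit cases", {
  # competitive: no inhibitor, I = K_i, I = 3 K_i
  expect_identical(competitive_km_multiplier(0, 5), 1)
  expect_identical(competitive_km_multiplier(2, 2), 2)
  expect_identical(competitive_km_multiplier(6, 2), 4)
  expect_error(competitive_km_multiplier(-1, 2), ">= 0")

  # mechanism-based: zero, half-saturation, saturation
  expect_identical(inactivation_rate(0, 3, 1), 0)
  expect_equal(inactivation_rate(1, 3, 1), 1.5)
  expect_equal(inactivation_rate(1e9, 3, 1), 3, tolerance = 1e-6)

  # induction: zero, half-maximal, saturation
  expect_identical(induction_multiplier(0, 8, 1), 1)
  expect_equal(induction_multiplier(0.34, 8, 0.34), 5)
  expect_equal(induction_multiplier(1e9, 8, 0.34), 9, tolerance = 1e-6)
})

test_that("multipliers are monotone in perpetrator concentration and continuous at 0", {
  set.seed(41)
  for (i in 1:25) {
    conc <- sort(runif(20, 0, 50))
    k <- runif(1, 0.1, 20)
    expect_true(all(diff(competitive_km_multiplier(conc, k)) >= 0))
    expect_true(all(diff(inactivation_rate(conc, runif(1, 0.1, 5), k)) >= 0))
    expect_true(all(diff(induction_multiplier(conc, runif(1, 0.5, 10), k)) >= 0))
  }
  eps <- 1e-12
  expect_equal(competitive_km_multiplier(eps, 1), 1, tolerance = 1e-9)
  expect_equal(inactivation_rate(eps, 1, 1), 0, tolerance = 1e-9)
  expect_equal(induction_multiplier(eps, 1, 1), 1, tolerance = 1e-9)
})

test_that("enzyme pool derivative has the stated fixed points", {
  st <- enzyme_pool_state("CYP2C19", "liver", amount = 1, kdeg_per_h = 0.026)
  expect_identical(enzyme_pool_derivative(st), 0)  # baseline steady state

  # constant inactivation: RK4 integration relaxes to analytic steady state
  kdeg <- 0.04
  lam <- 0.11
  m_ind <- 1.8
  target <- kdeg * m_ind / (kdeg + lam)
  f <- function(a) enzyme_pool_derivative(
    enzyme_pool_state("E", "liver", amount = a, kdeg_per_h = kdeg),
    inactivation_rate = lam, induction_multiplier = m_ind)
  a_end <- rk4_scalar(f, 1, t_end = 12 / (kdeg + lam), dt = 0.05)
  expect_equal(a_end, target, tolerance = 1e-3)

  # induction only: steady state equals the synthesis multiplier
  g <- function(a) enzyme_pool_derivative(
    enzyme_pool_state("E", "liver", amount = a, kdeg_per_h = kdeg),
    induction_multiplier = 3)
  expect_equal(rk4_scalar(g, 1, t_end = 400, dt = 0.2), 3, tolerance = 1e-3)
})

test_that("enzyme amount stays nonnegative under the derivative contract", {
  set.seed(42)
  for (i in 1:30) {
    kdeg <- runif(1, 0.005, 0.2)
    lam <- runif(1, 0, 5)
    mind <- 1 + runif(1, 0, 9)
    f <- function(a) enzyme_pool_derivative(
      enzyme_pool_state("E", "liver", amount = a, kdeg_per_h = kdeg),
      inactivation_rate = lam, induction_multiplier = mind)
    a <- rk4_scalar(f, runif(1, 0, 2), t_end = 50, dt = 0.1)
    expect_gte(a, 0)
  }
})

test_that("mechanism-specific parameters are validated", {
  expect_error(interaction_parameters("x", "CYP3A4", "competitive"),
               "ki_umol_L")
  expect_error(interaction_parameters("x", "CYP3A4", "mechanism_based",
                                      kinact_per_h = 1), "KI_umol_L")
  expect_error(interaction_parameters("x", "CYP3A4", "induction",
                                      emax = -1, ec50_umol_L = 1), "emax")
  ok <- interaction_parameters("x", "CYP3A4", "induction", emax = 2,
                               ec50_umol_L = 0.5)
  expect_s3_class(ok, "interaction_parameters")
})

test_that("engine enzyme pool reaches the analytic steady state under constant infusion", {
  # constant iv infusion of omeprazole -> constant unbound liver conc ->
  # CYP2C19 pool must settle at kdeg / (kdeg + lambda(Cu)) within 0.1%
  omep <- builtin_partners()$omeprazole
  mod <- add_partner_to_model(zero_rate_model(), omep)
  ind <- the_individual()
  reg <- regimen(list(dose_event("omeprazole", "iv", 40, 0,
                                 infusion_h = 600)), "infusion")
  sim <- simulate_pbpk(mod, ind, reg,
                       solver_settings(times = seq(0, 600, by = 5)))
  nT <- length(sim$times)
  liv_i <- (match("omeprazole", sim$compounds) - 1) * 7 +
    match("liver", PBPK_COMPARTMENTS)
  A_liv <- sim$y[nT, liv_i]
  cp <- mod$compounds$omeprazole
  V_liv <- ind$organs$liver$volume_L
  cu <- cp$fu * A_liv / (V_liv * cp$kp * ind$organs$liver$kp)
  ia <- omep$interactions[[1]]
  lam <- inactivation_rate(cu, ia$kinact_per_h, ia$KI_umol_L)
  kdeg <- ind$kdeg_per_h[["CYP2C19"]]
  pool <- unname(enzyme_pools(sim)[nT, "CYP2C19@liver"])
  expect_lt(lam, kdeg * 50)  # sanity: inactivation not fully saturated
  expect_gt(lam, 0)
  expect_equal(pool, kdeg / (kdeg + lam), tolerance = 1e-3)
})
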