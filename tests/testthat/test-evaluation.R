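test_that("MRD reproduces its worked examples", {
  expect_equal(as.numeric(mrd(c(10, 20, 30), c(10, 20, 30))), 1)
  expect_equal(as.numeric(mrd(10, 100)), 10)
  # two pairs with symmetric 2-fold errors: x = 0.30103, MRD = 2
  expect_equal(as.numeric(mrd(c(10, 100), c(20, 50))), 2, tolerance = 1e-12)
  # BLQ policy: zero observations are excluded and counted
  m <- mrd(c(0, 10), c(5, 10))
  expect_equal(as.numeric(m), 1)
  expect_identical(attr(m, "n_dropped"), 1L)
  expect_error(mrd(c(0, 0), c(1, 2)), "usable")
})

test_that("GMFE reproduces its worked examples", {
  expect_equal(gmfe(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(gmfe(5, 10), 2)
  # fold errors 2 and 0.5 do not cancel: absolute logs give 2
  expect_equal(gmfe(c(10, 10), c(20, 5)), 2)
  expect_error(gmfe(numeric(0), numeric(0)), "at least one")
  expect_error(gmfe(c(1, -1), c(1, 1)), "positive")
})

test_that("MRD and GMFE are scale-invariant and bounded below by 1", {
  set.seed(7)
  for (i in 1:20) {
    obs <- runif(8, 1, 500)
    pred <- obs * exp(rnorm(8, 0, 0.5))
    s <- runif(1, 0.001, 1000)
    expect_equal(as.numeric(mrd(obs, pred)), as.numeric(mrd(obs * s, pred * s)))
    expect_equal(gmfe(obs, pred), gmfe(obs * s, pred * s))
    expect_gte(as.numeric(mrd(obs, pred)), 1)
    expect_gte(gmfe(obs, pred), 1)
  }
})

test_that("interaction ratios and fold classification behave as stated", {
  expect_equal(interaction_ratio(0.5, 1), 0.5)
  expect_equal(interaction_ratio(3.9, 1), 3.9)
  expect_equal(interaction_ratio(7, 7), 1)
  expect_error(interaction_ratio(1, 0), "> 0")

  expect_true(gof_classify(19, 10, 2))
  expect_false(gof_classify(21, 10, 2))
  expect_true(gof_classify(12, 10, 1.25))
  expect_false(gof_classify(12.6, 10, 1.25))
  expect_error(gof_classify(-1, 10), "positive")
})

test_that("Guest limits reproduce closed-form cases and symmetry", {
  expect_equal(guest_limits(1), c(lower = 0.8, upper = 1.25))
  gl2 <- guest_limits(2)
  expect_equal(gl2, c(lower = 2 / 1.625, upper = 2 * 1.625))
  expect_equal(unname(gl2["lower"]), 1.2308, tolerance = 1e-4)
  gl05 <- guest_limits(0.5)
  expect_equal(unname(gl05["lower"]), 0.30769, tolerance = 1e-4)
  expect_equal(unname(gl05["upper"]), 0.8125, tolerance = 1e-4)
  # symmetry under R <-> 1/R and containment
  for (r in c(0.1, 0.25, 0.5, 0.9, 1, 1.4, 2, 5, 10)) {
    gl <- guest_limits(r)
    inv <- guest_limits(1 / r)
    expect_equal(unname(gl["lower"]), unname(1 / inv["upper"]))
    expect_true(gl["lower"] <= r && r <= gl["upper"])
    # contained in the 2-fold band wherever the width factor is <= 2
    L <- unname(gl["upper"] / r)
    if (L <= 2) {
      expect_gte(unname(gl["lower"]), r / 2 - 1e-12)
      expect_lte(unname(gl["upper"]), r * 2 + 1e-12)
    }
  }
  expect_error(guest_limits(0), "> 0")
})

test_that("ratio_result combines Guest and 2-fold verdicts", {
  rr <- ratio_result("DDI", "AUC_last", predicted_ratio = 2.5,
                     observed_ratio = 2)
  expect_true(rr$within_guest)
  expect_true(rr$within_twofold)
  rr2 <- ratio_result("DDI", "AUC_last", predicted_ratio = 3.3,
                      observed_ratio = 2)
  expect_false(rr2$within_guest)
  expect_true(rr2$within_twofold)
})

test_that("profile evaluation aggregates per-profile MRD and GMFE", {
  mod <- the_model()
  ind <- the_individual()
  d <- study_design(dosing_regimen(150, route = "po"), SPARSE_TIMES,
                    c("clopidogrel", "Clo-COOH"),
                    noise = noise_model(sigma = 0.15), seed = 21)
  profs <- generate_observed_profiles(mod, ind, d)
  ev <- evaluate_profiles(mod, ind, profs)
  expect_equal(ev$n_profiles, 2)
  expect_gte(ev$mean_mrd, 1)
  expect_true(all(ev$per_profile$mrd >= 1))
  expect_lte(ev$gof_auc_2fold, 2)
})

test_that("observed profiles round-trip through the tabular exchange format", {
  d <- study_design(dosing_regimen(75, route = "po", n = 3), SPARSE_TIMES,
                    "Clo-AM", phenotype = "IM",
                    noise = noise_model(sigma = 0.1), seed = 5,
                    study_id = "rt", dataset = "test")
  profs <- generate_observed_profiles(the_model(), the_individual(), d)
  path <- withr::local_tempfile(fileext = ".csv")
  write_profiles(profs, path)
  back <- read_profiles(path)
  orig <- profs[[1]]
  got <- back[[orig$study_id]]
  expect_equal(got$times_h, orig$times_h)
  expect_equal(got$conc_ng_ml, orig$conc_ng_ml)
  expect_identical(got$phenotype, "IM")
  expect_identical(got$dataset, "test")
  expect_length(got$regimen$events, 3)
})
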