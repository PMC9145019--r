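# Synthetic study-data generator: observed-like concentration-time profiles
# with the statistical structure the evaluation and fitting stages assume
# (sparse sampling, multiplicative lognormal residual noise, optional
# between-subject variability, BLQ censoring, phenotype strata).

#' Construct a residual/between-subject noise model
#'
#' Residual noise is multiplicative lognormal (concentrations stay strictly
#' positive so log-scale metrics remain defined); sigma defaults to 0.2.
#' Between-subject variability multiplies compound kp values per simulated
#' subject with log-scale sd omega. Concentrations below the BLQ threshold
#' are censored and dropped.
#'
#' @param sigma residual log-scale sd (>= 0)
#' @param omega between-subject log-scale sd (>= 0)
#' @param blq_ng_ml lower limit of quantification (ng/mL)
#' @return a `noise_model`
#' @export
noise_model <- function(sigma = 0.2, omega = 0, blq_ng_ml = 0) {
  assert_that(sigma >= 0 && omega >= 0, "noise sds must be >= 0")
  structure(list(sigma = sigma, omega = omega, blq_ng_ml = blq_ng_ml),
            class = "noise_model")
}

#' Construct a study design
#'
#' @param regimen a [regimen()]
#' @param sampling_times_h increasing sampling times (h)
#' @param compounds_measured compound names to report
#' @param n_subjects number of subjects (profiles are reported as the
#'   arithmetic mean across subjects, with sd, when > 1)
#' @param phenotype optional CYP2C19 phenotype of the cohort
#' @param noise a [noise_model()]
#' @param seed mandatory integer seed
#' @param study_id study label
#' @param dataset `"training"` or `"test"`
#' @return a `study_design`
#' @export
study_design <- function(regimen, sampling_times_h, compounds_measured,
                         n_subjects = 1L, phenotype = NA_character_,
                         noise = noise_model(), seed = 1L,
                         study_id = "synthetic", dataset = "training") {
  assert_that(all(diff(sampling_times_h) > 0),
              "sampling times must be increasing")
  assert_that(n_subjects >= 1, "need at least one subject")
  structure(list(regimen = regimen, sampling_times_h = sampling_times_h,
                 compounds_measured = compounds_measured,
                 n_subjects = as.integer(n_subjects), phenotype = phenotype,
                 noise = noise, seed = as.integer(seed),
                 study_id = study_id, dataset = dataset),
            class = "study_design")
}

#' Generate observed-like profiles from a model under a study design
#'
#' Simulates the design's regimen, samples the prediction at the design's
#' sampling times, applies per-point multiplicative lognormal residual
#' noise, censors below the BLQ threshold (dropped points), and averages
#' across subjects when `n_subjects > 1` (reporting the sd). Deterministic
#' given the design seed.
#'
#' @param model a `model_definition`
#' @param individual an `individual`
#' @param design a [study_design()]
#' @param settings [solver_settings()]
#' @return list of [observed_profile()]s, one per measured compound
#' @export
generate_observed_profiles <- function(model, individual, design,
                                       settings = solver_settings()) {
  assert_that(inherits(design, "study_design"), "not a study_design")
  set.seed(design$seed)
  ind <- if (!is.na(design$phenotype))
    set_phenotype(individual, design$phenotype) else individual
  st <- settings
  st$times <- sort(unique(c(0, design$sampling_times_h)))
  nz <- design$noise
  nt <- length(design$sampling_times_h)

  subject_sims <- lapply(seq_len(design$n_subjects), function(s) {
    m <- model
    if (nz$omega > 0) {
      for (cp in names(m$compounds)) {
        mult <- exp(rnorm(1, 0, nz$omega))
        m <- set_model_parameter(m, sprintf("kp|%s", cp),
                                 m$compounds[[cp]]$kp * mult)
      }
    }
    simulate_pbpk(m, ind, design$regimen, st)
  })

  lapply(setNames(nm = design$compounds_measured), function(cp) {
    draws <- vapply(subject_sims, function(sim)
      interpolate_prediction(sim$times, sim$conc[, cp],
                             design$sampling_times_h) *
        exp(rnorm(nt, 0, nz$sigma)),
      numeric(nt))
    draws <- matrix(draws, nrow = nt)
    mean_c <- rowMeans(draws)
    sd_c <- if (design$n_subjects > 1) apply(draws, 1, sd) else NULL
    keep <- mean_c >= nz$blq_ng_ml
    observed_profile(
      study_id = paste0(design$study_id, "_", cp),
      compound = cp,
      times_h = design$sampling_times_h[keep],
      conc_ng_ml = mean_c[keep],
      sd_ng_ml = if (is.null(sd_c)) NULL else sd_c[keep],
      n_subjects = design$n_subjects,
      regimen = design$regimen,
      phenotype = design$phenotype,
      dataset = design$dataset)
  })
}

#' Generate the packaged benchmark suite
#'
#' Emits a fixture set mirroring the clinical study mix the network was
#' developed on: iv single doses spanning 0.1-300 mg, oral single doses
#' 75-600 mg, an oral 75 mg daily multiple-dose arm, phenotype-stratified
#' (NM/IM/PM) active-metabolite profiles, and a DDI arm pair (omeprazole
#' co-treatment), plus a manifest with the ground-truth parameters for
#' recovery tests.
#'
#' @param seed integer seed; each study derives its own sub-seed
#' @param model optional model (default [clopidogrel_network()])
#' @param individual optional individual
#' @param sigma residual noise sd (default 0.2)
#' @param settings [solver_settings()]
#' @return a `benchmark_suite`: list with `profiles` (list of
#'   [observed_profile()]s), `manifest` (list with ground-truth parameter
#'   table and study table), `model`
#' @export
generate_benchmark_suite <- function(seed, model = NULL, individual = NULL,
                                     sigma = 0.2,
                                     settings = solver_settings()) {
  model <- model %||% clopidogrel_network()
  individual <- individual %||% build_reference_individual()
  rich <- c(0.25, 0.5, 1, 1.5, 2, 3, 4, 6, 8, 12, 16, 24)
  nz <- noise_model(sigma = sigma)
  designs <- list()
  add <- function(d) designs[[length(designs) + 1]] <<- d
  k <- 0
  subseed <- function() { k <<- k + 1; (seed * 1009L + k * 101L) %% 2147483647L }

  for (dose in c(0.1, 10, 300))
    add(study_design(dosing_regimen(dose, route = "iv"), rich,
                     c("clopidogrel", "Clo-COOH"), noise = nz,
                     seed = subseed(),
                     study_id = sprintf("iv_sd_%gmg", dose)))
  for (dose in c(75, 150, 300, 600))
    add(study_design(dosing_regimen(dose, route = "po"), rich,
                     c("clopidogrel", "Clo-COOH", "Clo-AG", "2-Oxo-Clo",
                       "Clo-AM"),
                     noise = nz, seed = subseed(),
                     study_id = sprintf("po_sd_%gmg", dose)))
  md_times <- c(216 + rich)  # sampling on day 10 of daily dosing
  add(study_design(dosing_regimen(75, route = "po", n = 10), md_times,
                   c("clopidogrel", "Clo-COOH", "Clo-AM"), noise = nz,
                   seed = subseed(), study_id = "po_md_75mg"))
  for (ph in c("NM", "IM", "PM"))
    add(study_design(dosing_regimen(300, route = "po"), rich,
                     c("clopidogrel", "Clo-AM"), phenotype = ph,
                     noise = nz, seed = subseed(),
                     study_id = sprintf("dgi_%s_300mg", ph),
                     dataset = "test"))

  profiles <- list()
  for (d in designs)
    profiles <- c(profiles, generate_observed_profiles(model, individual, d,
                                                       settings))

  # DDI arm pair: Clo-AM with and without omeprazole co-treatment
  omep <- builtin_partners()$omeprazole
  ddi_model <- add_partner_to_model(model, omep)
  clo_md <- lapply(0:4, function(i) dose_event("clopidogrel", "po", 75,
                                               i * 24))
  omep_md <- lapply(0:4, function(i) dose_event("omeprazole", "po", 80,
                                                i * 24))
  ddi_times <- 96 + rich
  for (arm in c("control", "ddi")) {
    evs <- if (arm == "control") clo_md else c(clo_md, omep_md)
    d <- study_design(regimen(evs, paste("ddi", arm)), ddi_times, "Clo-AM",
                      noise = nz, seed = subseed(),
                      study_id = paste0("ddi_omeprazole_", arm),
                      dataset = "test")
    profiles <- c(profiles,
                  generate_observed_profiles(ddi_model, individual, d,
                                             settings))
  }

  truth <- model_parameters(model)
  truth <- truth[truth$fittable, c("id", "value")]
  names(truth)[2] <- "true_value"
  manifest <- list(
    seed = seed, sigma = sigma,
    n_profiles = length(profiles),
    compounds = CLOPIDOGREL_COMPOUNDS,
    studies = data.frame(
      study_id = vapply(profiles, `[[`, character(1), "study_id"),
      compound = vapply(profiles, `[[`, character(1), "compound"),
      phenotype = vapply(profiles, `[[`, character(1), "phenotype"),
      n_points = vapply(profiles, function(p) length(p$times_h), integer(1))),
    truth = truth)
  structure(list(profiles = profiles, manifest = manifest, model = model),
            class = "benchmark_suite")
}

#' @export
print.benchmark_suite <- function(x, ...) {
  cat("<benchmark_suite>", length(x$profiles), "profiles,",
      length(unique(x$manifest$studies$study_id)), "studies, seed",
      x$manifest$seed, "\n")
  invisible(x)
}

#' Write a benchmark suite to a directory
#'
#' Emits `profiles.csv` (tidy tabular profile format consumed by the
#' evaluation and fitting interfaces) and `manifest.json` (seed, noise
#' level, study table, ground-truth parameters).
#'
#' @param suite a `benchmark_suite`
#' @param dir output directory (created if absent)
#' @export
write_benchmark_suite <- function(suite, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_profiles(suite$profiles, file.path(dir, "profiles.csv"))
  write_json_config(suite$manifest, file.path(dir, "manifest.json"))
  invisible(dir)
}
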