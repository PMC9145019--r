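# Model evaluation statistics: mean relative deviation (MRD) of predicted
# concentrations, geometric mean fold error (GMFE) of PK parameters, 2-fold
# goodness-of-fit classification, interaction ratios, and the
# ratio-dependent Guest acceptance limits.

#' Construct an observed concentration-time profile
#'
#' The unit of evaluation: study metadata plus sampled concentrations
#' (digitized or synthetic).
#'
#' @param study_id study identifier
#' @param compound compound name
#' @param times_h sampling times (h), strictly increasing
#' @param conc_ng_ml concentrations (ng/mL, >= 0)
#' @param sd_ng_ml optional standard deviations
#' @param n_subjects number of subjects averaged
#' @param regimen optional [regimen()] that generated the profile
#' @param phenotype optional CYP2C19 phenotype
#' @param dataset `"training"` or `"test"`
#' @return an `observed_profile`
#' @export
observed_profile <- function(study_id, compound, times_h, conc_ng_ml,
                             sd_ng_ml = NULL, n_subjects = 1L,
                             regimen = NULL, phenotype = NA_character_,
                             dataset = c("training", "test")) {
  dataset <- match.arg(dataset)
  assert_that(length(times_h) == length(conc_ng_ml),
              "times and concentrations must match")
  assert_that(all(diff(times_h) > 0), "times must be strictly increasing")
  assert_that(all(conc_ng_ml >= 0), "concentrations must be >= 0")
  structure(list(study_id = study_id, compound = compound,
                 times_h = times_h, conc_ng_ml = conc_ng_ml,
                 sd_ng_ml = sd_ng_ml, n_subjects = as.integer(n_subjects),
                 regimen = regimen, phenotype = phenotype, dataset = dataset),
            class = "observed_profile")
}

#' Mean relative deviation of predicted concentrations
#'
#' `MRD = 10^x`, `x = sqrt( sum_i (log10 chat_i - log10 c_i)^2 / k )` over
#' the k usable observed/predicted pairs. Pairs in which either value is
#' nonpositive are excluded (below-limit-of-quantification policy: censor
#' and drop); the number of exclusions is reported as an attribute. MRD is
#' 1 for a perfect prediction and >= 1 always.
#'
#' @param observed observed concentrations, or an [observed_profile()]
#' @param predicted predicted concentrations matched to the observed
#'   sampling times
#' @return MRD (dimensionless), attribute `n_used`, `n_dropped`
#' @export
mrd <- function(observed, predicted) {
  if (inherits(observed, "observed_profile")) observed <- observed$conc_ng_ml
  assert_that(length(observed) == length(predicted),
              "observed and predicted must have equal length")
  ok <- observed > 0 & predicted > 0 & is.finite(observed) &
    is.finite(predicted)
  assert_that(sum(ok) > 0, "no usable observed/predicted pairs")
  x <- sqrt(mean((log10(predicted[ok]) - log10(observed[ok]))^2))
  structure(10^x, n_used = sum(ok), n_dropped = sum(!ok))
}

#' Geometric mean fold error of PK parameters
#'
#' `GMFE = 10^x`, `x = sum_i |log10(phat_i / p_i)| / m`: the absolute log
#' fold error averaged over studies. GMFE is 1 for perfect prediction and
#' >= 1 always; a single 2-fold error gives 2.
#'
#' @param observed observed PK parameter values (> 0), or a data.frame with
#'   columns `observed` and `predicted`
#' @param predicted predicted values (> 0)
#' @return GMFE (dimensionless)
#' @export
gmfe <- function(observed, predicted = NULL) {
  if (is.data.frame(observed)) {
    predicted <- observed$predicted
    observed <- observed$observed
  }
  assert_that(length(observed) >= 1, "need at least one prediction pair")
  assert_that(length(observed) == length(predicted),
              "observed and predicted must have equal length")
  assert_that(all(observed > 0) && all(predicted > 0),
              "GMFE requires positive values")
  10^mean(abs(log10(predicted / observed)))
}

#' Interaction PK-parameter ratio
#'
#' DGI: phenotype (IM or PM) over NM reference. DDI: victim with
#' perpetrator over victim control.
#'
#' @param pk_interaction AUC_last or C_max under interaction
#' @param pk_reference AUC_last or C_max of the reference arm (> 0)
#' @return the ratio
#' @export
interaction_ratio <- function(pk_interaction, pk_reference) {
  assert_that(all(pk_reference > 0), "reference PK parameter must be > 0")
  pk_interaction / pk_reference
}

#' Guest acceptance limits for interaction ratios
#'
#' Ratio-dependent bounds narrower than 2-fold near unity: with
#' `R' = max(R, 1/R)` and `delta = 1/(1 - variability)` (so 20% variability
#' widens the band at R = 1 to the familiar 0.80-1.25 range),
#' `L = (delta + 2 (R' - 1)) / R'` and the accepted band is `(R/L, R*L)`.
#' The band is symmetric under R <-> 1/R and always contains R.
#'
#' @param observed_ratio observed interaction ratio (> 0)
#' @param variability fractional variability (default 0.20)
#' @return named vector `c(lower, upper)`
#' @export
guest_limits <- function(observed_ratio, variability = 0.20) {
  assert_that(all(observed_ratio > 0), "ratio must be > 0")
  assert_that(variability >= 0 && variability < 1,
              "variability must be in [0, 1)")
  rp <- pmax(observed_ratio, 1 / observed_ratio)
  L <- (1 / (1 - variability) + 2 * (rp - 1)) / rp
  c(lower = observed_ratio / L, upper = observed_ratio * L)
}

#' Fold-deviation goodness-of-fit classification
#'
#' @param predicted predicted value (> 0)
#' @param observed observed value (> 0)
#' @param fold acceptance fold (1.25 or 2 in routine use)
#' @return TRUE iff `observed/fold <= predicted <= observed*fold`
#' @export
gof_classify <- function(predicted, observed, fold = 2.0) {
  assert_that(all(predicted > 0) && all(observed > 0),
              "goodness-of-fit requires positive values")
  predicted >= observed / fold & predicted <= observed * fold
}

#' Interpolate a predicted profile onto observed sampling times
#'
#' Linear in time on log-concentration where both bracketing predictions
#' are positive; linear on the natural scale otherwise.
#'
#' @param pred_times_h prediction time grid
#' @param pred_conc predicted concentrations
#' @param obs_times_h target times
#' @return predicted concentrations at `obs_times_h`
#' @export
interpolate_prediction <- function(pred_times_h, pred_conc, obs_times_h) {
  pos <- all(pred_conc > 0)
  if (pos) {
    10^approx(pred_times_h, log10(pred_conc), xout = obs_times_h,
              rule = 2)$y
  } else {
    approx(pred_times_h, pred_conc, xout = obs_times_h, rule = 2)$y
  }
}

#' Assemble a ratio result with Guest bounds
#'
#' @param ratio_type `"DGI"` or `"DDI"`
#' @param parameter `"AUC_last"` or `"C_max"`
#' @param predicted_ratio predicted interaction ratio
#' @param observed_ratio observed interaction ratio (may be NA when no
#'   observed arm exists; Guest bounds are then NA)
#' @param variability Guest variability (default 0.20)
#' @return a `ratio_result`
#' @export
ratio_result <- function(ratio_type = c("DGI", "DDI"),
                         parameter = c("AUC_last", "C_max"),
                         predicted_ratio, observed_ratio = NA_real_,
                         variability = 0.20) {
  ratio_type <- match.arg(ratio_type)
  parameter <- match.arg(parameter)
  if (is.finite(observed_ratio)) {
    gl <- guest_limits(observed_ratio, variability)
    within_guest <- predicted_ratio >= gl["lower"] &
      predicted_ratio <= gl["upper"]
    within_twofold <- gof_classify(predicted_ratio, observed_ratio, 2)
  } else {
    gl <- c(lower = NA_real_, upper = NA_real_)
    within_guest <- NA
    within_twofold <- NA
  }
  structure(list(ratio_type = ratio_type, parameter = parameter,
                 predicted_ratio = predicted_ratio,
                 observed_ratio = observed_ratio,
                 guest_lower = unname(gl["lower"]),
                 guest_upper = unname(gl["upper"]),
                 within_guest = unname(within_guest),
                 within_twofold = unname(within_twofold)),
            class = "ratio_result")
}

#' @export
print.ratio_result <- function(x, ...) {
  cat(sprintf("%s %s ratio: predicted %.3g", x$ratio_type, x$parameter,
              x$predicted_ratio))
  if (is.finite(x$observed_ratio))
    cat(sprintf(", observed %.3g, Guest (%.3g, %.3g), within: %s",
                x$observed_ratio, x$guest_lower, x$guest_upper,
                x$within_guest))
  cat("\n")
  invisible(x)
}

#' Evaluate a set of observed profiles against model predictions
#'
#' For each profile the model is simulated under the profile's regimen and
#' phenotype, the prediction is interpolated onto the observed sampling
#' times, and MRD plus AUC_last/C_max prediction pairs over the observed
#' window are computed. Aggregation mirrors the usual reporting shape:
#' per-profile MRD with their mean, and GMFE over AUC_last and C_max
#' separately.
#'
#' @param model a `model_definition`
#' @param individual an `individual`
#' @param profiles list of [observed_profile()]s (each must carry a regimen)
#' @param settings [solver_settings()]
#' @return an `evaluation_report` with elements `per_profile` (data.frame),
#'   `mean_mrd`, `gmfe_auc`, `gmfe_cmax`, `gof_auc_2fold`, `gof_cmax_2fold`
#' @export
evaluate_profiles <- function(model, individual, profiles,
                              settings = solver_settings()) {
  rows <- lapply(profiles, function(pr) {
    assert_that(inherits(pr, "observed_profile"), "not an observed_profile")
    assert_that(!is.null(pr$regimen), "profile carries no regimen")
    ind <- if (!is.na(pr$phenotype)) set_phenotype(individual, pr$phenotype)
           else individual
    st <- settings
    # simulate on the regular grid augmented with the exact observed times so
    # predictions at observed samples carry no interpolation error
    st$times <- sort(unique(c(seq(0, max(pr$times_h), by = st$dt),
                              pr$times_h)))
    sim <- simulate_pbpk(model, ind, pr$regimen, st)
    pred <- interpolate_prediction(sim$times, sim$conc[, pr$compound],
                                   pr$times_h)
    m <- mrd(pr$conc_ng_ml, pred)
    obs_pk <- pk_metrics(pr$times_h, pr$conc_ng_ml)
    pred_pk <- pk_metrics(pr$times_h, pred)
    data.frame(study_id = pr$study_id, compound = pr$compound,
               dataset = pr$dataset, mrd = as.numeric(m),
               n_used = attr(m, "n_used"),
               obs_auc = obs_pk$AUC_last, pred_auc = pred_pk$AUC_last,
               obs_cmax = obs_pk$C_max, pred_cmax = pred_pk$C_max)
  })
  tab <- do.call(rbind, rows)
  ok_auc <- tab$obs_auc > 0 & tab$pred_auc > 0
  structure(list(
    per_profile = tab,
    mean_mrd = mean(tab$mrd),
    gmfe_auc = if (any(ok_auc)) gmfe(tab$obs_auc[ok_auc], tab$pred_auc[ok_auc])
               else NA_real_,
    gmfe_cmax = gmfe(tab$obs_cmax, tab$pred_cmax),
    gof_auc_2fold = sum(gof_classify(tab$pred_auc[ok_auc],
                                     tab$obs_auc[ok_auc], 2)),
    gof_cmax_2fold = sum(gof_classify(tab$pred_cmax, tab$obs_cmax, 2)),
    n_profiles = nrow(tab)
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>", x$n_profiles, "profiles\n")
  cat(sprintf("  mean MRD %.3f | GMFE AUC_last %.3f | GMFE Cmax %.3f\n",
              x$mean_mrd, x$gmfe_auc, x$gmfe_cmax))
  cat(sprintf("  within 2-fold: AUC_last %d, Cmax %d of %d\n",
              x$gof_auc_2fold, x$gof_cmax_2fold, x$n_profiles))
  invisible(x)
}

#' Write observed profiles to a tidy CSV
#'
#' Columns: study_id, compound, time_h, conc_ng_ml, sd_ng_ml, n, phenotype,
#' dataset, plus the regimen encoded as amount_mg/route/n_doses/interval_h
#' (single-compound regimens only, which covers study designs emitted by the
#' synthetic-data generator).
#'
#' @param profiles list of [observed_profile()]s
#' @param path output CSV path
#' @export
write_profiles <- function(profiles, path) {
  tab <- do.call(rbind, lapply(profiles, function(pr) {
    ev <- pr$regimen$events
    data.frame(study_id = pr$study_id, compound = pr$compound,
               time_h = pr$times_h, conc_ng_ml = pr$conc_ng_ml,
               sd_ng_ml = if (is.null(pr$sd_ng_ml)) NA_real_ else pr$sd_ng_ml,
               n = pr$n_subjects,
               phenotype = pr$phenotype, dataset = pr$dataset,
               dose_compound = ev[[1]]$compound,
               amount_mg = ev[[1]]$amount_mg, route = ev[[1]]$route,
               n_doses = length(ev),
               interval_h = if (length(ev) > 1)
                 ev[[2]]$time_h - ev[[1]]$time_h else 24)
  }))
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Read observed profiles from a tidy CSV (inverse of [write_profiles()])
#' @param path CSV path
#' @return list of `observed_profile`s
#' @export
read_profiles <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  lapply(split(tab, tab$study_id), function(d) {
    d <- d[order(d$time_h), ]
    reg <- dosing_regimen(d$amount_mg[1], compound = d$dose_compound[1],
                          route = d$route[1], n = d$n_doses[1],
                          interval_h = d$interval_h[1])
    observed_profile(d$study_id[1], d$compound[1], d$time_h, d$conc_ng_ml,
                     sd_ng_ml = if (all(is.na(d$sd_ng_ml))) NULL else d$sd_ng_ml,
                     n_subjects = d$n[1], regimen = reg,
                     phenotype = if (is.na(d$phenotype[1])) NA_character_
                                 else d$phenotype[1],
                     dataset = d$dataset[1])
  })
}
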