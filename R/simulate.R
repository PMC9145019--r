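# Simulation engine: assembles the coupled ODE system (compounds x
# compartments + enzyme pools), applies dose events, integrates with the
# compiled adaptive Runge-Kutta core, and derives PK metrics and mass
# balance summaries. Internal state is in micromol; plasma concentrations
# are reported in ng/mL via the molecular weight; time is in hours.

ORGAN_INDEX <- setNames(seq_along(PBPK_COMPARTMENTS) - 1L, PBPK_COMPARTMENTS)
ENZYME_ORGANS <- c("gut_wall", "liver", "kidney")

#' Construct a dose event
#'
#' @param compound compound name
#' @param route `"iv"` (into venous blood) or `"po"` (into gut lumen)
#' @param amount_mg dose in mg (>= 0)
#' @param time_h administration time in h (>= 0)
#' @param infusion_h infusion duration in h; 0 means bolus
#' @return a `dose_event`
#' @export
dose_event <- function(compound, route = c("po", "iv"), amount_mg,
                       time_h = 0, infusion_h = 0) {
  route <- match.arg(route)
  assert_that(amount_mg >= 0, "dose amount must be >= 0")
  assert_that(time_h >= 0, "dose time must be >= 0")
  assert_that(infusion_h >= 0, "infusion duration must be >= 0")
  structure(list(compound = compound, route = route, amount_mg = amount_mg,
                 time_h = time_h, infusion_h = infusion_h),
            class = "dose_event")
}

#' Construct a dosing regimen
#'
#' @param events a list of [dose_event()]s (any order; sorted by time)
#' @param label free-text label
#' @return a `regimen`
#' @export
regimen <- function(events, label = "") {
  assert_that(all(vapply(events, inherits, logical(1), "dose_event")),
              "events must be dose_event objects")
  events <- events[order(vapply(events, `[[`, numeric(1), "time_h"))]
  structure(list(events = events, label = label), class = "regimen")
}

#' Single- and multiple-dose regimen shortcuts
#'
#' @param amount_mg dose per administration in mg
#' @param compound compound name
#' @param route `"po"` or `"iv"`
#' @param n number of administrations
#' @param interval_h dosing interval in h
#' @param start_h time of first dose
#' @return a `regimen`
#' @export
dosing_regimen <- function(amount_mg, compound = "clopidogrel",
                           route = "po", n = 1, interval_h = 24,
                           start_h = 0) {
  events <- lapply(seq_len(n) - 1, function(i)
    dose_event(compound, route, amount_mg, start_h + i * interval_h))
  regimen(events, label = sprintf("%s %g mg %s x%d", compound, amount_mg,
                                  route, n))
}

#' Default solver settings
#'
#' @param t_end simulation end time in h (default: 24 h after last dose)
#' @param dt output grid spacing in h
#' @param times explicit output time grid (overrides t_end/dt)
#' @param rtol,atol relative/absolute solver tolerances
#' @param hmax maximal solver step (h)
#' @param maxsteps step budget per dose segment
#' @return a list of settings
#' @export
solver_settings <- function(t_end = NULL, dt = 0.1, times = NULL,
                            rtol = 1e-8, atol = 1e-10, hmax = 5,
                            maxsteps = 5e6) {
  list(t_end = t_end, dt = dt, times = times, rtol = rtol, atol = atol,
       hmax = hmax, maxsteps = as.integer(maxsteps))
}

# Flatten model + individual into the array form consumed by the C++ core.
compile_pbpk <- function(model, individual) {
  comps <- names(model$compounds)
  nc <- length(comps)
  enz <- PBPK_ENZYMES
  ne <- length(enz)
  organs <- individual$organs
  V <- vapply(organs, `[[`, numeric(1), "volume_L")

  Kp <- matrix(1, nc, length(PBPK_COMPARTMENTS),
               dimnames = list(comps, PBPK_COMPARTMENTS))
  for (cp in model$compounds)
    for (k in c("gut_wall", "liver", "kidney", "rest"))
      Kp[cp$name, k] <- cp$kp * organs[[k]]$kp

  E <- matrix(0, ne, length(PBPK_COMPARTMENTS),
              dimnames = list(enz, PBPK_COMPARTMENTS))
  E[rownames(individual$expressions), colnames(individual$expressions)] <-
    individual$expressions

  act <- setNames(rep(1, ne), enz)
  act["CYP2C19"] <- phenotype_activity(individual$cyp2c19_phenotype)

  p_type <- integer(); p_sub <- integer(); p_prod <- integer()
  p_org <- integer(); p_enz <- integer()
  p_km <- numeric(); p_kcat <- numeric(); p_cl <- numeric()
  labels <- character()
  cidx <- function(x) match(x, comps) - 1L
  eidx <- function(x) match(x, enz) - 1L

  for (p in model$processes) {
    sites <- ENZYME_ORGANS[E[p$enzyme, ENZYME_ORGANS] > 0]
    for (k in sites) {
      p_type <- c(p_type, 0L)
      p_sub <- c(p_sub, cidx(p$substrate))
      p_prod <- c(p_prod, if (is.na(p$product)) -1L else cidx(p$product))
      p_org <- c(p_org, ORGAN_INDEX[[k]])
      p_enz <- c(p_enz, eidx(p$enzyme))
      p_km <- c(p_km, p$km_umol_L)
      p_kcat <- c(p_kcat, p$kcat_per_min * 60)  # 1/min -> 1/h
      p_cl <- c(p_cl, 0)
      labels <- c(labels, sprintf("mm|%s|%s->%s|%s", p$enzyme, p$substrate,
                                  ifelse(is.na(p$product), "sink", p$product), k))
    }
  }
  for (cl in model$clearances) {
    k <- if (cl$site == "hepatic") "liver" else "kidney"
    is_enz <- !is.na(cl$enzyme)
    p_type <- c(p_type, if (is_enz) 2L else 1L)
    p_sub <- c(p_sub, cidx(cl$compound))
    p_prod <- c(p_prod, if (is.na(cl$product)) -1L else cidx(cl$product))
    p_org <- c(p_org, ORGAN_INDEX[[k]])
    p_enz <- c(p_enz, if (is_enz) eidx(cl$enzyme) else -1L)
    p_km <- c(p_km, 0); p_kcat <- c(p_kcat, 0)
    p_cl <- c(p_cl, cl$cl_L_per_h)
    labels <- c(labels, sprintf("cl|%s|%s%s", cl$compound, cl$site,
                                ifelse(is_enz, paste0("|", cl$enzyme), "")))
  }

  ias <- model$interactions
  mech_code <- c(competitive = 0L, mechanism_based = 1L, induction = 2L)
  i_perp <- vapply(ias, function(x) cidx(x$perpetrator), integer(1))
  i_enz <- vapply(ias, function(x) eidx(x$enzyme), integer(1))
  i_mech <- vapply(ias, function(x) mech_code[[x$mechanism]], integer(1))
  fin0 <- function(v) ifelse(is.finite(v), v, 1)
  i_ki <- fin0(vapply(ias, `[[`, numeric(1), "ki_umol_L"))
  i_kinact <- vapply(ias, function(x)
    if (is.finite(x$kinact_per_h)) x$kinact_per_h else 0, numeric(1))
  i_KI <- fin0(vapply(ias, `[[`, numeric(1), "KI_umol_L"))
  i_emax <- vapply(ias, function(x)
    if (is.finite(x$emax)) x$emax else 0, numeric(1))
  i_ec50 <- fin0(vapply(ias, `[[`, numeric(1), "ec50_umol_L"))

  # enzyme pools at every expressed (enzyme, organ) site
  pool_map <- matrix(-1L, ne, length(PBPK_COMPARTMENTS))
  pool_enz <- integer(); pool_org <- integer(); pool_lab <- character()
  for (e in seq_len(ne)) for (k in ENZYME_ORGANS) {
    if (E[e, k] > 0) {
      pool_map[e, ORGAN_INDEX[[k]] + 1L] <- length(pool_enz)
      pool_enz <- c(pool_enz, e - 1L)
      pool_org <- c(pool_org, ORGAN_INDEX[[k]])
      pool_lab <- c(pool_lab, paste0(enz[e], "@", k))
    }
  }

  engine <- list(
    nc = nc, ne = ne,
    V = unname(V),
    Q_gut = organs$gut_wall$flow_L_per_h,
    Q_ha = organs$liver$flow_L_per_h,
    Q_kid = organs$kidney$flow_L_per_h,
    Q_rest = organs$rest$flow_L_per_h,
    fu = vapply(model$compounds, `[[`, numeric(1), "fu"),
    ka = vapply(model$compounds, `[[`, numeric(1), "ka_per_h"),
    ktr = vapply(model$compounds, `[[`, numeric(1), "ktr_per_h"),
    Kp = as.numeric(t(Kp)),  # row-major nc x 7
    E = as.numeric(t(E)),
    kdeg = unname(individual$kdeg_per_h[enz]),
    act = unname(act),
    p_type = p_type, p_sub = p_sub, p_prod = p_prod, p_org = p_org,
    p_enz = p_enz, p_km = p_km, p_kcat = p_kcat, p_cl = p_cl,
    i_perp = as.integer(i_perp), i_enz = as.integer(i_enz),
    i_mech = as.integer(i_mech),
    i_ki = as.numeric(i_ki), i_kinact = as.numeric(i_kinact),
    i_KI = as.numeric(i_KI), i_emax = as.numeric(i_emax),
    i_ec50 = as.numeric(i_ec50),
    pool_map = as.integer(t(pool_map)),
    pool_enz = pool_enz, pool_org = pool_org
  )
  np <- length(p_type); npool <- length(pool_enz)
  list(engine = engine, compounds = comps, enzymes = enz,
       process_labels = labels, pool_labels = pool_lab,
       mw = vapply(model$compounds, `[[`, numeric(1), "mw_g_mol"),
       np = np, npool = npool,
       off_fec = nc * 7L, off_abs = nc * 8L, off_flux = nc * 9L,
       off_pool = nc * 9L + np, ntot = nc * 9L + np + npool)
}

#' Simulate a dosing regimen
#'
#' Oral doses enter the gut lumen and traverse gut-wall metabolism before
#' portal delivery to the liver (intestinal then hepatic first pass);
#' intravenous doses enter venous blood. The integrator is deterministic
#' given configuration: there are no random elements in the engine.
#'
#' @param model a `model_definition`
#' @param individual an `individual`
#' @param regimen a [regimen()]
#' @param settings a [solver_settings()] list
#' @return a `pbpk_result` with the output time grid, per compound x
#'   compartment amounts (umol), plasma concentrations (ng/mL), cumulative
#'   process fluxes, and enzyme pools over time
#' @export
simulate_pbpk <- function(model, individual, regimen,
                          settings = solver_settings()) {
  findings <- validate_network(model, individual)
  assert_that(length(findings) == 0,
              paste("model failed validation:\n ",
                    paste(findings, collapse = "\n  ")))
  cm <- compile_pbpk(model, individual)
  nc <- cm$engine$nc

  events <- regimen$events
  ev_t <- vapply(events, `[[`, numeric(1), "time_h")
  last_t <- if (length(ev_t)) max(ev_t) else 0
  t_end <- settings$t_end %||% (last_t + 24)
  times <- settings$times %||% seq(0, t_end, by = settings$dt)
  times <- sort(unique(times))
  assert_that(all(diff(times) > 0) && times[1] >= 0,
              "output time grid must be strictly increasing and nonnegative")
  t_end <- max(times)

  # segment boundaries: dose times and infusion ends
  bounds <- sort(unique(c(0, ev_t[ev_t <= t_end],
                          (ev_t + vapply(events, `[[`, numeric(1),
                                         "infusion_h"))[ev_t <= t_end],
                          t_end)))
  bounds <- bounds[bounds <= t_end]

  y <- numeric(cm$ntot)
  if (cm$npool > 0) y[cm$off_pool + seq_len(cm$npool)] <- 1
  out <- matrix(NA_real_, length(times), cm$ntot)
  administered <- setNames(numeric(nc), cm$compounds)
  administered_po <- setNames(numeric(nc), cm$compounds)

  dose_umol <- function(ev) ev$amount_mg * 1000 / cm$mw[[ev$compound]]

  record0 <- times[1] == 0
  for (si in seq_len(length(bounds) - 1)) {
    t0 <- bounds[si]; t1 <- bounds[si + 1]
    ivrate <- numeric(nc); porate <- numeric(nc)
    for (ev in events) {
      assert_that(ev$compound %in% cm$compounds,
                  sprintf("dose event for undeclared compound '%s'",
                          ev$compound))
      ci <- match(ev$compound, cm$compounds)
      amt <- dose_umol(ev)
      if (ev$infusion_h == 0) {
        if (abs(ev$time_h - t0) < 1e-9) {
          slot <- if (ev$route == "iv") (ci - 1) * 7 + 1 else (ci - 1) * 7 + 3
          y[slot] <- y[slot] + amt
          administered[ci] <- administered[ci] + amt
          if (ev$route == "po")
            administered_po[ci] <- administered_po[ci] + amt
        }
      } else if (ev$time_h <= t0 + 1e-9 &&
                 ev$time_h + ev$infusion_h >= t1 - 1e-9) {
        rate <- amt / ev$infusion_h
        if (ev$route == "iv") ivrate[ci] <- ivrate[ci] + rate
        else porate[ci] <- porate[ci] + rate
        dt_seg <- t1 - t0
        administered[ci] <- administered[ci] + rate * dt_seg
        if (ev$route == "po")
          administered_po[ci] <- administered_po[ci] + rate * dt_seg
      }
    }
    if (record0 && t0 == 0) {
      out[1, ] <- y
      record0 <- FALSE
    }
    sel <- which(times > t0 + 1e-9 & times <= t1 + 1e-9)
    seg_times <- times[sel]
    if (length(seg_times) == 0 || max(seg_times) < t1 - 1e-9)
      seg_times <- c(seg_times, t1)
    res <- pbpk_integrate_cpp(cm$engine, y, t0, seg_times, ivrate, porate,
                              settings$rtol, settings$atol, settings$hmax,
                              settings$maxsteps)
    if (length(sel)) out[sel, ] <- res$y[seq_along(sel), ]
    y <- res$final
  }

  amounts <- out[, seq_len(nc * 7), drop = FALSE]
  conc <- sapply(seq_len(nc), function(ci)
    pmax(out[, (ci - 1) * 7 + 1], 0) /
      cm$engine$V[1] * cm$mw[ci])
  conc <- matrix(conc, nrow = length(times),
                 dimnames = list(NULL, cm$compounds))

  structure(list(
    times = times, y = out, conc = conc, amounts = amounts,
    compounds = cm$compounds, compartments = PBPK_COMPARTMENTS,
    process_labels = cm$process_labels, pool_labels = cm$pool_labels,
    compiled = cm, administered_umol = administered,
    administered_po_umol = administered_po,
    model = model, individual = individual, regimen = regimen,
    settings = settings
  ), class = "pbpk_result")
}

#' @export
print.pbpk_result <- function(x, ...) {
  cat("<pbpk_result>", length(x$times), "time points over",
      max(x$times), "h;", length(x$compounds), "compounds\n")
  cmax <- apply(x$conc, 2, max)
  for (cp in x$compounds)
    cat(sprintf("  %-12s Cmax %.4g ng/mL\n", cp, cmax[[cp]]))
  invisible(x)
}

#' Tidy data frame of a simulation result
#'
#' @param x a `pbpk_result`
#' @param row.names,optional,... ignored (S3 signature)
#' @return data.frame with columns time_h, compound, compartment,
#'   amount_umol, plasma_conc_ng_ml
#' @export
as.data.frame.pbpk_result <- function(x, row.names = NULL, optional = FALSE,
                                      ...) {
  nc <- length(x$compounds)
  nt <- length(x$times)
  do.call(rbind, lapply(seq_len(nc), function(ci) {
    do.call(rbind, lapply(seq_len(7), function(k) {
      data.frame(time_h = x$times, compound = x$compounds[ci],
                 compartment = PBPK_COMPARTMENTS[k],
                 amount_umol = x$amounts[, (ci - 1) * 7 + k],
                 plasma_conc_ng_ml = if (k == 1) x$conc[, ci] else NA_real_)
    }))
  }))
}

#' Plasma concentration-time profile of one compound
#' @param result a `pbpk_result`
#' @param compound compound name
#' @return data.frame with time_h and conc_ng_ml
#' @export
plasma_profile <- function(result, compound) {
  assert_that(compound %in% result$compounds,
              sprintf("compound '%s' not simulated", compound))
  data.frame(time_h = result$times, conc_ng_ml = result$conc[, compound])
}

#' Enzyme pool trajectories
#' @param result a `pbpk_result`
#' @return matrix time x pool (columns named enzyme@organ), relative amounts
#' @export
enzyme_pools <- function(result) {
  cm <- result$compiled
  if (cm$npool == 0) return(matrix(numeric(0), nrow = length(result$times)))
  m <- result$y[, cm$off_pool + seq_len(cm$npool), drop = FALSE]
  colnames(m) <- cm$pool_labels
  m
}

#' Cumulative process fluxes at end of simulation
#' @param result a `pbpk_result`
#' @return named numeric vector, umol
#' @export
process_fluxes <- function(result) {
  cm <- result$compiled
  fl <- result$y[nrow(result$y), cm$off_flux + seq_len(cm$np)]
  setNames(fl, cm$process_labels)
}

#' Noncompartmental PK metrics over an observation window
#'
#' AUC_last is computed by the linear trapezoidal rule between the first and
#' last sample of the window; C_max and t_max are taken over the same window.
#'
#' @param time_h sampling times (h), strictly increasing
#' @param conc concentrations (ng/mL)
#' @param t_first,t_last window bounds (default: full range of `time_h`)
#' @return a `pk_metrics` list with AUC_last (ng*h/mL), C_max (ng/mL),
#'   t_max (h) and the window
#' @export
pk_metrics <- function(time_h, conc, t_first = min(time_h),
                       t_last = max(time_h)) {
  assert_that(length(time_h) == length(conc) && length(time_h) >= 1,
              "need matching, nonempty time and concentration vectors")
  assert_that(all(diff(time_h) > 0), "times must be strictly increasing")
  sel <- time_h >= t_first - 1e-12 & time_h <= t_last + 1e-12
  assert_that(any(sel), "empty observation window")
  tt <- time_h[sel]; cc <- conc[sel]
  imax <- which.max(cc)
  structure(list(
    AUC_last = if (length(tt) > 1) trapz(tt, cc) else 0,
    C_max = cc[imax], t_max = tt[imax],
    window = c(t_first = min(tt), t_last = max(tt))
  ), class = "pk_metrics")
}

#' @export
print.pk_metrics <- function(x, ...) {
  cat(sprintf("AUC_last %.5g ng*h/mL, Cmax %.5g ng/mL at t %.3g h (window %g-%g h)\n",
              x$AUC_last, x$C_max, x$t_max, x$window[1], x$window[2]))
  invisible(x)
}

#' Mass balance and fraction-metabolized report
#'
#' Accounts for every administered mole: remaining in the body, unabsorbed
#' (faeces), and eliminated through each sink process. For the network
#' parent (clopidogrel when present) it additionally reports the fraction
#' of dose absorbed and the split of absorbed parent between the CES pathway
#' (to Clo-COOH) and the CYP pathway (to 2-Oxo-Clo).
#'
#' @param result a `pbpk_result`
#' @param parent parent compound name (default "clopidogrel" when present)
#' @return a `mass_balance` list
#' @export
mass_balance_report <- function(result, parent = NULL) {
  cm <- result$compiled
  nc <- cm$engine$nc
  yT <- result$y[nrow(result$y), ]
  in_body <- vapply(seq_len(nc), function(ci)
    sum(pmax(yT[(ci - 1) * 7 + seq_len(7)], 0)), numeric(1))
  feces <- yT[cm$off_fec + seq_len(nc)]
  absorbed <- yT[cm$off_abs + seq_len(nc)]
  names(in_body) <- names(feces) <- names(absorbed) <- cm$compounds
  flux <- setNames(yT[cm$off_flux + seq_len(cm$np)], cm$process_labels)
  # a process is a sink when moles leave the system: metabolic processes
  # without product, and clearances without product (partner-stub enzyme
  # clearances may carry a product, e.g. bupropion -> hydroxybupropion)
  sink <- grepl("->sink\\|", names(flux)) | startsWith(names(flux), "cl|")
  prod_cl <- vapply(result$model$clearances, function(cl)
    !is.na(cl$product), logical(1))
  if (any(prod_cl)) {
    with_prod <- sprintf("cl|%s|%s|%s",
                         vapply(result$model$clearances[prod_cl], `[[`,
                                character(1), "compound"),
                         vapply(result$model$clearances[prod_cl], `[[`,
                                character(1), "site"),
                         vapply(result$model$clearances[prod_cl], `[[`,
                                character(1), "enzyme"))
    sink[names(flux) %in% with_prod] <- FALSE
  }
  administered <- result$administered_umol
  total_in <- sum(administered)
  total_accounted <- sum(in_body) + sum(feces) + sum(flux[sink])
  gap <- if (total_in > 0) (total_in - total_accounted) / total_in else 0

  parent <- parent %||%
    (if ("clopidogrel" %in% cm$compounds) "clopidogrel" else cm$compounds[1])
  po_dose <- result$administered_po_umol[[parent]]
  basis <- absorbed[[parent]] +
    (administered[[parent]] - po_dose)  # absorbed po + all iv
  f_abs <- if (po_dose > 0) absorbed[[parent]] / po_dose else NA_real_
  ces_flux <- sum(flux[grepl(sprintf("^mm\\|CES[12]\\|%s->", parent),
                             names(flux))])
  cyp_flux <- sum(flux[grepl(sprintf("^mm\\|CYP\\w+\\|%s->2-Oxo-Clo",
                                     parent), names(flux))])
  structure(list(
    administered_umol = administered,
    in_body_umol = in_body,
    feces_umol = feces,
    absorbed_umol = absorbed,
    eliminated_umol = flux[sink],
    balance_rel_error = gap,
    parent = parent,
    fraction_absorbed = f_abs,
    fraction_to_ces = if (basis > 0) ces_flux / basis else NA_real_,
    fraction_to_2oxo = if (basis > 0) cyp_flux / basis else NA_real_
  ), class = "mass_balance")
}

#' @export
print.mass_balance <- function(x, ...) {
  cat("<mass_balance> relative gap", format(x$balance_rel_error, digits = 3),
      "\n")
  if (is.finite(x$fraction_absorbed))
    cat(sprintf("  %s: fraction absorbed %.3f\n", x$parent,
                x$fraction_absorbed))
  if (is.finite(x$fraction_to_2oxo))
    cat(sprintf("  absorbed %s -> CES pathway %.3f, -> 2-Oxo-Clo %.3f\n",
                x$parent, x$fraction_to_ces, x$fraction_to_2oxo))
  invisible(x)
}
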