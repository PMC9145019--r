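# Compound and metabolic-network definitions: the executable form of the
# clopidogrel parent-metabolite pathway map.

CLOPIDOGREL_COMPOUNDS <- c("clopidogrel", "Clo-COOH", "Clo-AG",
                           "2-Oxo-Clo", "Clo-AM")

#' Construct a compound
#'
#' @param name compound identifier
#' @param mw_g_mol molecular weight in g/mol (> 0)
#' @param fu fraction unbound in plasma, in (0, 1]
#' @param kp scalar tissue-to-plasma partition coefficient applied to all
#'   non-blood organs (multiplied by any organ-level kp); may be derived
#'   from lipophilicity via [kp_from_lipophilicity()] but an explicit value
#'   always wins
#' @param logp lipophilicity (log units), informational unless kp is NULL
#' @param ka_per_h first-order absorption rate from gut lumen (1/h); 0 for
#'   compounds never dosed orally
#' @param ktr_per_h luminal transit rate to faeces (1/h)
#' @param solubility_mg_L optional aqueous solubility, informational
#' @return a `compound`
#' @export
compound <- function(name, mw_g_mol, fu, kp = NULL, logp = NA_real_,
                     ka_per_h = 0, ktr_per_h = 0.06,
                     solubility_mg_L = NA_real_) {
  assert_that(is.character(name) && nzchar(name), "compound needs a name")
  assert_that(mw_g_mol > 0, sprintf("%s: molecular weight must be > 0", name))
  assert_that(fu > 0 && fu <= 1,
              sprintf("%s: fraction unbound must be in (0, 1]", name))
  if (is.null(kp)) {
    assert_that(is.finite(logp),
                sprintf("%s: supply kp or logp to derive it", name))
    kp <- kp_from_lipophilicity(logp, fu)
  }
  assert_that(kp > 0, sprintf("%s: kp must be > 0", name))
  assert_that(ka_per_h >= 0 && ktr_per_h >= 0,
              sprintf("%s: absorption/transit rates must be >= 0", name))
  structure(list(name = name, mw_g_mol = mw_g_mol, fu = fu, kp = kp,
                 logp = logp, ka_per_h = ka_per_h, ktr_per_h = ktr_per_h,
                 solubility_mg_L = solubility_mg_L),
            class = "compound")
}

#' Derive a partition coefficient from lipophilicity
#'
#' Single documented empirical rule used only when no explicit kp is
#' configured: `kp = 0.5 + fu^-0.2 * 10^(0.3 * logp - 0.5)`, a monotone map
#' giving hydrophilic compounds kp near 0.5-1 and lipophilic compounds kp in
#' the tens. Configured kp values always take precedence.
#'
#' @param logp lipophilicity (log units)
#' @param fu fraction unbound
#' @return scalar kp
#' @export
kp_from_lipophilicity <- function(logp, fu = 1) {
  assert_that(is.finite(logp), "logp must be finite")
  0.5 + fu^-0.2 * 10^(0.3 * logp - 0.5)
}

#' Construct a Michaelis-Menten metabolic process
#'
#' The process is enzyme-level: at simulation time it is instantiated in
#' every organ where the enzyme is expressed, with maximal velocity
#' `k_cat * activity * pool * [E] * V_organ`.
#'
#' @param substrate substrate compound name
#' @param product product compound name, or `NA` for a sink (moles leave the
#'   system, tracked as cumulative flux)
#' @param enzyme enzyme identifier
#' @param km_umol_L Michaelis constant (umol/L, unbound; > 0),
#'   literature-fixed by convention
#' @param kcat_per_min catalytic rate constant (1/min; >= 0), the fitted
#'   quantity of the network
#' @param fittable whether k_cat is a fitted-parameter slot
#' @return a `metabolic_process`
#' @export
metabolic_process <- function(substrate, product, enzyme, km_umol_L,
                              kcat_per_min, fittable = TRUE) {
  assert_that(km_umol_L > 0, "K_M must be > 0")
  assert_that(kcat_per_min >= 0, "k_cat must be >= 0")
  assert_that(is.na(product) || !identical(substrate, product),
              "a compound cannot be its own metabolite")
  structure(list(substrate = substrate, product = product, enzyme = enzyme,
                 km_umol_L = km_umol_L, kcat_per_min = kcat_per_min,
                 fittable = isTRUE(fittable)),
            class = "metabolic_process")
}

#' Construct a nonspecific clearance process
#'
#' Clearance convention: `cl_L_per_h` acts on the unbound concentration in
#' the site organ (liver for hepatic, kidney for renal), i.e. flux =
#' CL * fu * C_organ / Kp in umol/h. When `enzyme` is given the clearance is
#' additionally scaled by that enzyme's relative active pool and activity
#' fraction (linear enzyme-mediated elimination, used by interaction-partner
#' stubs) and is subject to competitive inhibition of the enzyme.
#'
#' @param compound compound name
#' @param site `"hepatic"` or `"renal"`
#' @param cl_L_per_h clearance (L/h, unbound-referenced; >= 0)
#' @param enzyme optional mediating enzyme
#' @param product optional product compound (default sink)
#' @param fittable whether the clearance is a fitted-parameter slot
#' @return a `clearance_process`
#' @export
clearance_process <- function(compound, site = c("hepatic", "renal"),
                              cl_L_per_h, enzyme = NA_character_,
                              product = NA_character_, fittable = TRUE) {
  site <- match.arg(site)
  assert_that(cl_L_per_h >= 0, "clearance must be >= 0")
  structure(list(compound = compound, site = site, cl_L_per_h = cl_L_per_h,
                 enzyme = enzyme, product = product,
                 fittable = isTRUE(fittable)),
            class = "clearance_process")
}

#' Assemble a model definition
#'
#' @param compounds list of [compound()]s
#' @param processes list of [metabolic_process()]es
#' @param clearances list of [clearance_process()]es
#' @param interactions list of [interaction_parameters()] blocks
#' @return a `model_definition`
#' @export
model_definition <- function(compounds, processes = list(),
                             clearances = list(), interactions = list()) {
  names(compounds) <- vapply(compounds, `[[`, character(1), "name")
  assert_that(!anyDuplicated(names(compounds)), "duplicate compound names")
  md <- structure(list(compounds = compounds, processes = processes,
                       clearances = clearances, interactions = interactions),
                  class = "model_definition")
  for (p in processes) {
    assert_that(p$substrate %in% names(compounds),
                sprintf("process substrate '%s' not declared", p$substrate))
    assert_that(is.na(p$product) || p$product %in% names(compounds),
                sprintf("process product '%s' not declared", p$product))
  }
  for (cl in clearances)
    assert_that(cl$compound %in% names(compounds),
                sprintf("clearance compound '%s' not declared", cl$compound))
  md
}

#' @export
print.model_definition <- function(x, ...) {
  cat("<model_definition>", length(x$compounds), "compounds,",
      length(x$processes), "metabolic processes,",
      length(x$clearances), "clearances,",
      length(x$interactions), "interaction blocks\n")
  for (p in x$processes)
    cat(sprintf("  %s -> %s via %s (KM %.3g uM, kcat %.4g /min)\n",
                p$substrate, ifelse(is.na(p$product), "[sink]", p$product),
                p$enzyme, p$km_umol_L, p$kcat_per_min))
  for (cl in x$clearances)
    cat(sprintf("  CL %s %s%s -> %s (%.4g L/h)\n", cl$site, cl$compound,
                ifelse(is.na(cl$enzyme), "", paste0(" via ", cl$enzyme)),
                ifelse(is.na(cl$product), "[sink]", cl$product),
                cl$cl_L_per_h))
  invisible(x)
}

#' Build the clopidogrel parent-metabolite network
#'
#' Constructs the five-compound network: clopidogrel is hydrolysed to its
#' carboxylic acid (Clo-COOH) by CES1 (liver) and CES2 (intestinal mucosa
#' only); Clo-COOH is glucuronidated to Clo-AG by UGT2B7 with renal excretion
#' of Clo-AG; in parallel, CYP2C19 and CYP3A4 oxidise clopidogrel to
#' 2-oxo-clopidogrel and further to the active thiol metabolite (Clo-AM).
#' 2-Oxo-Clo carries a nonspecific hepatic sink clearance (inactive thiol
#' formation) and Clo-AM a nonspecific hepatic sink clearance (irreversible
#' platelet binding). Autoinhibition edges (clopidogrel on CYP2B6/CYP2C19,
#' Clo-AG on CYP2C8) are included and individually toggleable via the
#' `enabled` column of the interaction table.
#'
#' @param parameter_source optional list with elements `compounds`,
#'   `processes`, `interactions`, each a data frame or CSV path overriding
#'   the packaged parameter tables (which carry a provenance column)
#' @return a `model_definition`
#' @export
clopidogrel_network <- function(parameter_source = NULL) {
  src <- parameter_source %||% list()
  load_tab <- function(x, default)
    if (is.null(x)) read.csv(clopbpk_extdata(default), stringsAsFactors = FALSE)
    else if (is.character(x)) read.csv(x, stringsAsFactors = FALSE)
    else as.data.frame(x)
  ctab <- load_tab(src$compounds, "clopidogrel_compounds.csv")
  ptab <- load_tab(src$processes, "clopidogrel_processes.csv")
  itab <- load_tab(src$interactions, "clopidogrel_interactions.csv")

  missing <- setdiff(CLOPIDOGREL_COMPOUNDS, ctab$name)
  assert_that(length(missing) == 0,
              paste("parameter source missing compounds:",
                    paste(missing, collapse = ", ")))
  compounds <- lapply(seq_len(nrow(ctab)), function(i)
    compound(ctab$name[i], ctab$mw_g_mol[i], fu = ctab$fu[i],
             kp = ctab$kp[i], logp = ctab$logp[i],
             ka_per_h = ctab$ka_per_h[i], ktr_per_h = ctab$ktr_per_h[i]))

  processes <- list(); clearances <- list()
  for (i in seq_len(nrow(ptab))) {
    row <- ptab[i, ]
    if (row$kind == "mm") {
      assert_that(is.finite(row$km_umol_L) && is.finite(row$kcat_per_min),
                  sprintf("row %d: missing K_M or k_cat", i))
      processes[[length(processes) + 1]] <- metabolic_process(
        row$substrate, if (is.na(row$product) || !nzchar(row$product)) NA_character_ else row$product,
        row$enzyme, row$km_umol_L, row$kcat_per_min,
        fittable = isTRUE(row$fittable))
    } else if (row$kind == "clearance") {
      assert_that(is.finite(row$cl_L_per_h),
                  sprintf("row %d: missing clearance value", i))
      clearances[[length(clearances) + 1]] <- clearance_process(
        row$substrate, row$site, row$cl_L_per_h,
        fittable = isTRUE(row$fittable))
    } else stop("unknown process kind: ", row$kind, call. = FALSE)
  }

  interactions <- list()
  for (i in seq_len(nrow(itab))) {
    row <- itab[i, ]
    if (!isTRUE(row$enabled)) next
    interactions[[length(interactions) + 1]] <- interaction_parameters(
      perpetrator = row$perpetrator, enzyme = row$enzyme,
      mechanism = row$mechanism,
      ki_umol_L = row$ki_umol_L, kinact_per_h = row$kinact_per_h,
      KI_umol_L = row$ki_half_umol_L, emax = row$emax,
      ec50_umol_L = row$ec50_umol_L)
  }

  model_definition(compounds, processes, clearances, interactions)
}

#' Validate a model against an individual
#'
#' Reporting operation: collects dangling compound references, enzymes with
#' zero expression in every organ, and nonpositive kinetic parameters. The
#' model is runnable iff the report is empty.
#'
#' @param model a `model_definition`
#' @param individual an `individual`
#' @return character vector of findings (length 0 when clean)
#' @export
validate_network <- function(model, individual) {
  findings <- character()
  comps <- names(model$compounds)
  expr <- individual$expressions
  for (p in model$processes) {
    if (!p$substrate %in% comps)
      findings <- c(findings, sprintf("substrate '%s' not declared", p$substrate))
    if (!is.na(p$product) && !p$product %in% comps)
      findings <- c(findings, sprintf("product '%s' not declared", p$product))
    if (!p$enzyme %in% rownames(expr))
      findings <- c(findings, sprintf("enzyme '%s' unknown to the physiology", p$enzyme))
    else if (all(expr[p$enzyme, ] == 0))
      findings <- c(findings, sprintf("enzyme '%s' has zero expression everywhere", p$enzyme))
    if (!is.finite(p$km_umol_L) || p$km_umol_L <= 0)
      findings <- c(findings, sprintf("process %s->%s: K_M must be > 0",
                                      p$substrate, p$product))
    if (!is.finite(p$kcat_per_min) || p$kcat_per_min < 0)
      findings <- c(findings, sprintf("process %s->%s: k_cat must be >= 0",
                                      p$substrate, p$product))
  }
  for (cl in model$clearances) {
    if (!cl$compound %in% comps)
      findings <- c(findings, sprintf("clearance compound '%s' not declared", cl$compound))
    if (!is.finite(cl$cl_L_per_h) || cl$cl_L_per_h < 0)
      findings <- c(findings, sprintf("clearance of '%s': value must be >= 0", cl$compound))
    if (!is.na(cl$enzyme) && (!cl$enzyme %in% rownames(expr) ||
                              all(expr[cl$enzyme, ] == 0)))
      findings <- c(findings, sprintf("clearance enzyme '%s' unexpressed", cl$enzyme))
  }
  for (ia in model$interactions) {
    if (!ia$perpetrator %in% comps)
      findings <- c(findings, sprintf("interaction perpetrator '%s' not declared", ia$perpetrator))
    if (!ia$enzyme %in% rownames(expr))
      findings <- c(findings, sprintf("interaction enzyme '%s' unknown", ia$enzyme))
  }
  # cycle check on the metabolic graph
  edges <- do.call(rbind, lapply(model$processes, function(p)
    if (!is.na(p$product)) c(p$substrate, p$product)))
  if (!is.null(edges) && has_cycle(edges))
    findings <- c(findings, "metabolic process graph contains a cycle")
  findings
}

has_cycle <- function(edges) {
  nodes <- unique(c(edges))
  state <- setNames(rep(0L, length(nodes)), nodes)  # 0 new, 1 open, 2 done
  adj <- split(edges[, 2], edges[, 1])
  visit <- function(n) {
    if (state[[n]] == 1L) return(TRUE)
    if (state[[n]] == 2L) return(FALSE)
    state[[n]] <<- 1L
    for (m in adj[[n]] %||% character()) if (visit(m)) return(TRUE)
    state[[n]] <<- 2L
    FALSE
  }
  any(vapply(nodes, visit, logical(1)))
}

#' Fittable parameter table of a model
#'
#' Parameter ids follow the scheme `kcat|<enzyme>|<substrate>`,
#' `cl|<compound>|<site>`, `kp|<compound>`, `ka|<compound>`,
#' `fu|<compound>`. K_M values are literature-fixed by convention and are
#' not listed as fittable.
#'
#' @param model a `model_definition`
#' @return data.frame with columns id, value, fittable
#' @export
model_parameters <- function(model) {
  rows <- list()
  for (p in model$processes)
    rows[[length(rows) + 1]] <- data.frame(
      id = sprintf("kcat|%s|%s", p$enzyme, p$substrate),
      value = p$kcat_per_min, fittable = p$fittable)
  for (cl in model$clearances)
    rows[[length(rows) + 1]] <- data.frame(
      id = sprintf("cl|%s|%s", cl$compound, cl$site),
      value = cl$cl_L_per_h, fittable = cl$fittable)
  for (cp in model$compounds) {
    rows[[length(rows) + 1]] <- data.frame(
      id = sprintf("kp|%s", cp$name), value = cp$kp, fittable = TRUE)
    rows[[length(rows) + 1]] <- data.frame(
      id = sprintf("ka|%s", cp$name), value = cp$ka_per_h,
      fittable = cp$ka_per_h > 0)
    rows[[length(rows) + 1]] <- data.frame(
      id = sprintf("fu|%s", cp$name), value = cp$fu, fittable = FALSE)
  }
  do.call(rbind, rows)
}

#' Set a model parameter by id
#' @param model a `model_definition`
#' @param id parameter id as listed by [model_parameters()]
#' @param value new value
#' @return the modified model
#' @export
set_model_parameter <- function(model, id, value) {
  parts <- strsplit(id, "|", fixed = TRUE)[[1]]
  kind <- parts[1]
  if (kind == "kcat") {
    for (i in seq_along(model$processes)) {
      p <- model$processes[[i]]
      if (p$enzyme == parts[2] && p$substrate == parts[3]) {
        model$processes[[i]]$kcat_per_min <- value
        return(model)
      }
    }
  } else if (kind == "cl") {
    for (i in seq_along(model$clearances)) {
      cl <- model$clearances[[i]]
      if (cl$compound == parts[2] && cl$site == parts[3]) {
        model$clearances[[i]]$cl_L_per_h <- value
        return(model)
      }
    }
  } else if (kind %in% c("kp", "ka", "fu")) {
    cp <- parts[2]
    if (cp %in% names(model$compounds)) {
      field <- c(kp = "kp", ka = "ka_per_h", fu = "fu")[[kind]]
      model$compounds[[cp]][[field]] <- value
      return(model)
    }
  }
  stop("unknown parameter id: ", id, call. = FALSE)
}

#' Get a model parameter by id
#' @param model a `model_definition`
#' @param id parameter id
#' @return current value
#' @export
get_model_parameter <- function(model, id) {
  tab <- model_parameters(model)
  hit <- match(id, tab$id)
  assert_that(!is.na(hit), paste("unknown parameter id:", id))
  tab$value[hit]
}

#' Serialize a model definition to a plain list
#' @param model a `model_definition`
#' @return JSON-compatible list
#' @export
model_to_list <- function(model) {
  list(
    compounds = lapply(model$compounds, unclass),
    processes = lapply(model$processes, unclass),
    clearances = lapply(model$clearances, unclass),
    interactions = lapply(model$interactions, unclass)
  )
}

#' Write a model definition to JSON
#' @param model a `model_definition`
#' @param path output path
#' @export
write_model <- function(model, path) write_json_config(model_to_list(model), path)

#' Read a model definition from JSON (round-trip inverse of [write_model()])
#' @param path JSON path
#' @return a `model_definition`
#' @export
read_model <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  num_or_na <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
  chr_or_na <- function(v) if (is.null(v)) NA_character_ else as.character(v)
  compounds <- lapply(x$compounds, function(cp)
    compound(cp$name, cp$mw_g_mol, fu = cp$fu, kp = cp$kp,
             logp = num_or_na(cp$logp), ka_per_h = cp$ka_per_h,
             ktr_per_h = cp$ktr_per_h,
             solubility_mg_L = num_or_na(cp$solubility_mg_L)))
  processes <- lapply(x$processes, function(p)
    metabolic_process(p$substrate, chr_or_na(p$product), p$enzyme,
                      p$km_umol_L, p$kcat_per_min, fittable = p$fittable))
  clearances <- lapply(x$clearances, function(cl)
    clearance_process(cl$compound, cl$site, cl$cl_L_per_h,
                      enzyme = chr_or_na(cl$enzyme),
                      product = chr_or_na(cl$product), fittable = cl$fittable))
  interactions <- lapply(x$interactions, function(ia)
    interaction_parameters(ia$perpetrator, ia$enzyme, ia$mechanism,
                           ki_umol_L = num_or_na(ia$ki_umol_L),
                           kinact_per_h = num_or_na(ia$kinact_per_h),
                           KI_umol_L = num_or_na(ia$KI_umol_L),
                           emax = num_or_na(ia$emax),
                           ec50_umol_L = num_or_na(ia$ec50_umol_L)))
  model_definition(compounds, processes, clearances, interactions)
}
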