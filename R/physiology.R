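# Reduced whole-body physiology: compartment scaffold, enzyme expression,
# CYP2C19 phenotype handling.

#' Compartment names of the reduced physiology
#'
#' The scaffold is deliberately small: venous and arterial blood, gut lumen,
#' gut wall (intestinal mucosa), liver, kidney, and one lumped rest-of-body
#' compartment. All implemented mechanisms (intestinal and hepatic first-pass
#' metabolism, renal excretion, enzyme turnover) live in these compartments;
#' the lumped remainder preserves mass balance and distribution volume.
#' @export
PBPK_COMPARTMENTS <- c("venous_blood", "arterial_blood", "gut_lumen",
                       "gut_wall", "liver", "kidney", "rest")

#' Enzymes known to the clopidogrel network and its interaction partners
#' @export
PBPK_ENZYMES <- c("CES1", "CES2", "UGT2B7", "CYP2C19", "CYP3A4",
                  "CYP2B6", "CYP2C8")

#' CYP2C19 phenotype activity fractions (activity scores 2/1/0)
#' @export
CYP2C19_ACTIVITY <- c(NM = 1.0, IM = 0.5, PM = 0.0)

#' Construct an organ specification
#'
#' @param name organ identifier
#' @param volume_L organ volume in litres (> 0)
#' @param flow_L_per_h plasma flow in L/h (>= 0; ignored for blood/lumen)
#' @param kp organ-level tissue-to-plasma partition multiplier (> 0); the
#'   effective Kp of a compound in an organ is `compound kp * organ kp`
#' @return an `organ_spec` list
#' @export
organ_spec <- function(name, volume_L, flow_L_per_h = 0, kp = 1) {
  assert_that(is.character(name) && nzchar(name), "organ needs a name")
  assert_that(is.numeric(volume_L) && volume_L > 0,
              sprintf("organ '%s': volume must be > 0", name))
  assert_that(flow_L_per_h >= 0,
              sprintf("organ '%s': blood flow must be >= 0", name))
  assert_that(kp > 0, sprintf("organ '%s': kp must be > 0", name))
  structure(list(name = name, volume_L = volume_L,
                 flow_L_per_h = flow_L_per_h, kp = kp),
            class = "organ_spec")
}

#' Build the reference virtual individual
#'
#' Loads the shipped physiology configuration (73 kg adult European male)
#' unless a configuration list or JSON file path is supplied. The returned
#' individual carries a complete enzyme-expression matrix: every enzyme of
#' the clopidogrel network has an entry (possibly zero) in every organ.
#'
#' CES2 expression is restricted to the intestinal mucosa; configurations
#' that place CES2 elsewhere are rejected, since intestinal confinement of
#' CES2 is what produces the dominant intestinal first-pass extraction of
#' clopidogrel.
#'
#' @param config `NULL` (use packaged default), a path to a JSON physiology
#'   file, or an equivalent list with elements `organs`, `expressions`,
#'   `body_weight_kg`, `gfr_L_per_h`, `kdeg_per_h`, `cyp2c19_phenotype`
#' @return an `individual` object
#' @export
build_reference_individual <- function(config = NULL) {
  if (is.null(config)) config <- clopbpk_extdata("physiology_default.json")
  if (is.character(config)) config <- read_json_config(config)

  org_df <- as.data.frame(config$organs)
  assert_that(!anyDuplicated(org_df$name), "organ names must be unique")
  missing_comp <- setdiff(PBPK_COMPARTMENTS, org_df$name)
  assert_that(length(missing_comp) == 0,
              paste("physiology config missing organs:",
                    paste(missing_comp, collapse = ", ")))
  org_df <- org_df[match(PBPK_COMPARTMENTS, org_df$name), ]
  if (is.null(org_df$kp)) org_df$kp <- 1
  organs <- lapply(seq_len(nrow(org_df)), function(i)
    organ_spec(org_df$name[i], org_df$volume_L[i], org_df$flow_L_per_h[i],
               org_df$kp[i]))
  names(organs) <- org_df$name

  expr <- matrix(0, nrow = length(PBPK_ENZYMES),
                 ncol = length(PBPK_COMPARTMENTS),
                 dimnames = list(PBPK_ENZYMES, PBPK_COMPARTMENTS))
  ex_df <- as.data.frame(config$expressions)
  for (i in seq_len(nrow(ex_df))) {
    e <- ex_df$enzyme[i]; o <- ex_df$organ[i]; v <- ex_df$conc_umol_per_L[i]
    assert_that(o %in% PBPK_COMPARTMENTS,
                sprintf("expression entry references unknown organ '%s'", o))
    assert_that(v >= 0, "enzyme expression must be >= 0")
    if (!e %in% PBPK_ENZYMES) next  # unknown enzymes tolerated, ignored
    expr[e, o] <- v
  }
  ces2_elsewhere <- expr["CES2", setdiff(colnames(expr), "gut_wall")]
  assert_that(all(ces2_elsewhere == 0),
              "CES2 expression must be confined to the intestinal mucosa")

  kdeg <- setNames(rep(0.03, length(PBPK_ENZYMES)), PBPK_ENZYMES)
  if (!is.null(config$kdeg_per_h)) {
    kd <- unlist(config$kdeg_per_h)
    kdeg[names(kd)[names(kd) %in% PBPK_ENZYMES]] <-
      kd[names(kd) %in% PBPK_ENZYMES]
  }
  assert_that(all(kdeg > 0), "enzyme turnover kdeg must be > 0")

  ind <- structure(list(
    organs = organs,
    expressions = expr,
    kdeg_per_h = kdeg,
    body_weight_kg = config$body_weight_kg %||% 73,
    gfr_L_per_h = config$gfr_L_per_h %||% 7.2,
    cyp2c19_phenotype = config$cyp2c19_phenotype %||% "NM"
  ), class = "individual")
  set_phenotype(ind, ind$cyp2c19_phenotype)
}

#' Set the CYP2C19 phenotype of an individual
#'
#' Phenotype scaling acts exclusively on CYP2C19 catalytic rate constants:
#' during simulation every CYP2C19 k_cat is multiplied by the activity
#' fraction (NM 100%, IM 50%, PM 0%) while K_M values are left untouched.
#'
#' @param individual an `individual`
#' @param phenotype one of `"NM"`, `"IM"`, `"PM"`
#' @return the modified individual
#' @export
set_phenotype <- function(individual, phenotype) {
  assert_that(inherits(individual, "individual"), "not an individual")
  assert_that(is.character(phenotype) && phenotype %in% names(CYP2C19_ACTIVITY),
              sprintf("unknown CYP2C19 phenotype '%s' (use NM, IM or PM)",
                      paste(phenotype, collapse = ",")))
  individual$cyp2c19_phenotype <- phenotype
  individual
}

#' CYP2C19 phenotype activity fraction
#'
#' Maps phenotype to the assumed relative activity derived from activity
#' scores: NM (score 2) 100%, IM (score 1) 50%, PM (score 0) 0%.
#'
#' @param phenotype one of `"NM"`, `"IM"`, `"PM"`
#' @return activity fraction in `[0, 1]`
#' @export
phenotype_activity <- function(phenotype) {
  assert_that(length(phenotype) == 1 && phenotype %in% names(CYP2C19_ACTIVITY),
              sprintf("unknown CYP2C19 phenotype '%s'",
                      paste(phenotype, collapse = ",")))
  unname(CYP2C19_ACTIVITY[phenotype])
}

#' Query enzyme expression of an individual
#'
#' @param individual an `individual`
#' @param enzyme enzyme identifier
#' @param organ organ identifier
#' @return expression in umol enzyme per L organ tissue
#' @export
get_expression <- function(individual, enzyme, organ) {
  assert_that(enzyme %in% rownames(individual$expressions),
              sprintf("unknown enzyme '%s'", enzyme))
  assert_that(organ %in% colnames(individual$expressions),
              sprintf("unknown organ '%s'", organ))
  individual$expressions[enzyme, organ]
}

#' @export
print.individual <- function(x, ...) {
  cat("<individual>", x$body_weight_kg, "kg, GFR", x$gfr_L_per_h,
      "L/h, CYP2C19", x$cyp2c19_phenotype, "\n")
  vols <- vapply(x$organs, `[[`, numeric(1), "volume_L")
  cat("  organs:", paste(sprintf("%s=%.2gL", names(vols), vols),
                         collapse = " "), "\n")
  expressed <- which(x$expressions > 0, arr.ind = TRUE)
  cat("  expressed enzyme sites:", nrow(expressed), "\n")
  invisible(x)
}

#' Serialize an individual to a plain list (JSON-compatible)
#' @param individual an `individual`
#' @return a list mirroring the physiology configuration schema
#' @export
individual_to_list <- function(individual) {
  org <- do.call(rbind, lapply(individual$organs, function(o)
    data.frame(name = o$name, volume_L = o$volume_L,
               flow_L_per_h = o$flow_L_per_h, kp = o$kp)))
  idx <- which(individual$expressions >= 0, arr.ind = TRUE)
  ex <- data.frame(enzyme = rownames(individual$expressions)[idx[, 1]],
                   organ = colnames(individual$expressions)[idx[, 2]],
                   conc_umol_per_L = individual$expressions[idx])
  ex <- ex[ex$conc_umol_per_L > 0, ]
  list(body_weight_kg = individual$body_weight_kg,
       gfr_L_per_h = individual$gfr_L_per_h,
       cyp2c19_phenotype = individual$cyp2c19_phenotype,
       organs = org, expressions = ex,
       kdeg_per_h = as.list(individual$kdeg_per_h))
}

#' Write an individual to a JSON physiology file
#' @param individual an `individual`
#' @param path output path
#' @export
write_individual <- function(individual, path) {
  write_json_config(individual_to_list(individual), path)
}

#' Read an individual from a JSON physiology file
#' @param path JSON file
#' @return an `individual`
#' @export
read_individual <- function(path) build_reference_individual(path)
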