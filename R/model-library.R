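# Structural model registry: named assemblies of the PKPD building blocks,
# selectable from a configuration file.  Each builder returns an
# endpoint_model whose fn is fully vectorised over subjects; steady-state
# endpoints use the analytic closed forms rather than long ODE simulation.

.conc_factor <- function(units) {
  cu <- units$concentration %||% "mg/L"
  if (!identical(units$dose %||% "mg", "mg"))
    .stopf("model.units.dose: only 'mg' is supported")
  switch(cu,
    "mg/L" = 1,
    "ug/L" = 1000,
    "ng/mL" = 1000,
    .stopf("model.units.concentration: unknown unit '%s' (use mg/L, ug/L or ng/mL)", cu))
}

# Case-1-style assembly: one-compartment oral PK at steady state, free
# concentration in plasma (periphery) and brain (via kp_uu), saturable
# inhibition at both sites, and the derived per-subject 'balanced' endpoint:
# central activity normalised (inhibition >= 1 - 1/fold_elevation) while
# peripheral activity is preserved above a floor (default 10%).
.build_onecomp_emax_balance <- function(config) {
  factor <- .conc_factor(config$model$units)
  preserve_min <- config$model$options$preserve_min %||% 0.10
  endpoint_model(
    name = "onecomp_emax_balance",
    params = c("CL", "fu", "kp_uu", "EC50", "Emax", "fold_elevation"),
    endpoints = c("central_inhibition", "peripheral_preservation", "balanced"),
    fn = function(P, reg, covariates = NULL) {
      css <- (reg$dose / (P[, "CL"] * reg$tau)) * factor
      c_free <- css * P[, "fu"]
      c_brain <- c_free * P[, "kp_uu"]
      ic <- P[, "Emax"] * c_brain / (P[, "EC50"] + c_brain)
      ip <- P[, "Emax"] * c_free / (P[, "EC50"] + c_free)
      preserve <- 1 - ip
      req <- 1 - 1 / P[, "fold_elevation"]
      cbind(central_inhibition = ic,
            peripheral_preservation = preserve,
            balanced = as.numeric(ic >= req & preserve >= preserve_min))
    })
}

# Case-2-style assembly: one-compartment oral PK at steady state driving a
# stimulation-of-production turnover model.  At steady state the biomarker
# fold-increase over baseline is 1 + E(Css) independent of the baseline
# itself, so the endpoint is computed in closed form; total Css doubles as
# the safety (exposure) endpoint.
.build_onecomp_turnover_stim <- function(config) {
  factor <- .conc_factor(config$model$units)
  endpoint_model(
    name = "onecomp_turnover_stim",
    params = c("CL", "Emax", "EC50"),
    endpoints = c("fold_increase", "css"),
    fn = function(P, reg, covariates = NULL) {
      css <- (reg$dose / (P[, "CL"] * reg$tau)) * factor
      fold <- 1 + P[, "Emax"] * css / (P[, "EC50"] + css)
      cbind(fold_increase = fold, css = css)
    })
}

# Case-3-style assembly: steady-state average exposure under linear +
# target-mediated (Michaelis-Menten) elimination, translated to tissue by a
# plasma-to-tissue distribution coefficient, driving an Imax
# indirect-response model whose steady-state fractional protein reduction is
# Imax * Ct / (IC50 + Ct).  Nonlinear elimination makes concentration units
# non-arbitrary, so this model requires mg/L.
.build_tmdd_indirect <- function(config) {
  if (!identical(config$model$units$concentration %||% "mg/L", "mg/L"))
    .stopf("model 'tmdd_indirect' requires concentration unit mg/L (Km is a concentration)")
  endpoint_model(
    name = "tmdd_indirect",
    params = c("CL", "Vmax", "Km", "Kp_tissue", "Imax", "IC50"),
    endpoints = c("protein_reduction", "css"),
    fn = function(P, reg, covariates = NULL) {
      css <- css_average_mm(reg, P[, "CL"], P[, "Vmax"], P[, "Km"])
      ct <- css * P[, "Kp_tissue"]
      red <- P[, "Imax"] * ct / (P[, "IC50"] + ct)
      cbind(protein_reduction = red, css = css)
    })
}

# Population-PK exposure summary: steady-state AUC over one dosing interval
# (dose/CL for linear elimination) and the corresponding average
# concentration.  Used by the target-attainment workflow.
.build_onecomp_pk_auc <- function(config) {
  factor <- .conc_factor(config$model$units)
  endpoint_model(
    name = "onecomp_pk_auc",
    params = "CL",
    endpoints = c("auc_tau", "css"),
    fn = function(P, reg, covariates = NULL) {
      auc <- (reg$dose / P[, "CL"]) * factor
      cbind(auc_tau = auc, css = auc / reg$tau)
    })
}

.model_defs <- function() list(
  onecomp_emax_balance = list(
    params = c("CL", "fu", "kp_uu", "EC50", "Emax", "fold_elevation"),
    endpoints = c("central_inhibition", "peripheral_preservation", "balanced"),
    builder = .build_onecomp_emax_balance),
  onecomp_turnover_stim = list(
    params = c("CL", "Emax", "EC50"),
    endpoints = c("fold_increase", "css"),
    builder = .build_onecomp_turnover_stim),
  tmdd_indirect = list(
    params = c("CL", "Vmax", "Km", "Kp_tissue", "Imax", "IC50"),
    endpoints = c("protein_reduction", "css"),
    builder = .build_tmdd_indirect),
  onecomp_pk_auc = list(
    params = "CL",
    endpoints = c("auc_tau", "css"),
    builder = .build_onecomp_pk_auc))

#' Available structural models
#'
#' Names of the structural model assemblies a configuration's
#' `model.structure` may select, and their required parameters / produced
#' endpoints.
#'
#' @return `pops_models()`: character vector of model names.
#' @export
pops_models <- function() names(.model_defs())

#' @rdname pops_models
#' @param name a model name.
#' @return `pops_model_info()`: list with `params` and `endpoints`.
#' @export
pops_model_info <- function(name) {
  defs <- .model_defs()
  if (!name %in% names(defs))
    .stopf("unknown structural model '%s' (known models: %s)",
           name, paste(names(defs), collapse = ", "))
  defs[[name]][c("params", "endpoints")]
}

.build_model <- function(config) {
  defs <- .model_defs()
  name <- config$model$structure
  if (is.null(name) || !name %in% names(defs))
    .stopf("unknown structural model '%s' (known models: %s)",
           name %||% "<missing>", paste(names(defs), collapse = ", "))
  defs[[name]]$builder(config)
}
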