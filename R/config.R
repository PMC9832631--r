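# Configuration schema, validation and assembly.  Configurations are plain
# nested lists (read from YAML) with sections: model, uncertainty, criteria,
# plan, and optionally scenarios / pta / meta.

.check_keys <- function(x, allowed, path) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    .stopf("unknown configuration key(s): %s",
           paste(paste0(path, ".", unknown), collapse = ", "))
}

.validate_run_config <- function(config) {
  .check_keys(config, c("case", "meta", "model", "uncertainty", "criteria",
                        "plan", "scenarios"), "config")
  for (sec in c("model", "criteria", "plan"))
    if (is.null(config[[sec]])) .stopf("missing configuration section '%s'", sec)

  m <- config$model
  .check_keys(m, c("structure", "units", "typical", "options"), "model")
  info <- pops_model_info(m$structure %||% "<missing>")
  m$units <- m$units %||% list()
  .check_keys(m$units, c("dose", "concentration", "time"), "model.units")
  m$units$dose <- m$units$dose %||% "mg"
  m$units$concentration <- m$units$concentration %||% "mg/L"
  m$units$time <- m$units$time %||% "h"
  if (!m$units$time %in% c("h", "day"))
    .stopf("model.units.time must be 'h' or 'day'")
  .conc_factor(m$units)
  config$model <- m

  u <- config$uncertainty %||% list()
  .check_keys(u, c("fixed", "correlation", "bsv"), "uncertainty")
  for (p in names(u$fixed))
    tryCatch(as_dist(u$fixed[[p]]), error = function(e)
      .stopf("uncertainty.fixed.%s: %s", p, conditionMessage(e)))
  known <- union(names(m$typical), names(u$fixed))
  missing_p <- setdiff(info$params, known)
  if (length(missing_p))
    .stopf("model '%s' needs parameter(s) %s in model.typical or uncertainty.fixed",
           m$structure, paste(missing_p, collapse = ", "))
  extra_p <- setdiff(names(u$fixed), info$params)
  if (length(extra_p))
    .stopf("uncertainty.fixed names parameter(s) not in model '%s': %s",
           m$structure, paste(extra_p, collapse = ", "))
  if (!is.null(u$bsv)) {
    .check_keys(u$bsv, c("cv", "correlation", "scale"), "uncertainty.bsv")
    u$bsv$scale <- u$bsv$scale %||% "lognormal"
    for (p in names(u$bsv$cv)) {
      v <- u$bsv$cv[[p]]
      if (is.numeric(v) && length(v) == 1L && (!is.finite(v) || v < 0))
        .stopf("uncertainty.bsv.cv.%s: CV must be >= 0", p)
      if (!p %in% info$params)
        .stopf("uncertainty.bsv.cv.%s: not a parameter of model '%s'",
               p, m$structure)
    }
  }
  config$uncertainty <- u

  if (length(config$criteria) == 0L)
    .stopf("at least one criterion is required")
  if (is.null(names(config$criteria)) || any(names(config$criteria) == ""))
    .stopf("criteria must be a named map (label -> criterion)")
  for (lab in names(config$criteria)) {
    cr <- config$criteria[[lab]]
    .check_keys(cr, c("endpoint", "comparator", "threshold",
                      "required_proportion", "kind", "boundary", "label"),
                paste0("criteria.", lab))
    if (is.null(cr$endpoint) || !cr$endpoint %in% info$endpoints)
      .stopf("criteria.%s.endpoint: '%s' is not an endpoint of model '%s' (%s)",
             lab, cr$endpoint %||% "<missing>", m$structure,
             paste(info$endpoints, collapse = ", "))
    config$criteria[[lab]]$label <- cr$label %||% lab
  }

  pl <- config$plan
  .check_keys(pl, c("M", "N", "doses", "tau", "route", "n_doses", "seed",
                    "common_rng"), "plan")
  pl$M <- pl$M %||% 500L
  pl$N <- pl$N %||% 1000L
  pl$seed <- pl$seed %||% 1L
  pl$tau <- pl$tau %||% 24
  pl$route <- pl$route %||% "oral"
  pl$n_doses <- pl$n_doses %||% 1L
  pl$common_rng <- pl$common_rng %||% TRUE
  config$plan <- pl
  # materialise the plan once to trigger its own validation
  do.call(simulation_plan, pl[c("doses", "M", "N", "seed", "tau", "route",
                                "n_doses", "common_rng")])

  if (!is.null(config$scenarios))
    .check_keys(config$scenarios, c("axes", "overrides"), "scenarios")
  config
}

.validate_pta_config <- function(config) {
  .check_keys(config, c("case", "meta", "plan", "pta"), "config")
  pta <- config$pta
  .check_keys(pta, c("candidate", "benchmark", "index", "n",
                     "target_quantile", "seed"), "pta")
  for (side in c("candidate", "benchmark")) {
    s <- pta[[side]]
    if (is.null(s)) .stopf("missing pta.%s", side)
    .check_keys(s, c("pk", "mic"), paste0("pta.", side))
    .check_keys(s$pk, c("CL", "dose", "tau", "cv_CL"),
                paste0("pta.", side, ".pk"))
    for (f in c("CL", "dose", "tau"))
      if (is.null(s$pk[[f]]))
        .stopf("missing pta.%s.pk.%s", side, f)
    if (!is.null(s$pk$cv_CL) && s$pk$cv_CL < 0)
      .stopf("pta.%s.pk.cv_CL must be >= 0", side)
    form <- s$mic$form %||% "<missing>"
    if (!form %in% c("logistic", "lognormal", "logistic_table"))
      .stopf("pta.%s.mic.form must be logistic, lognormal or logistic_table",
             side)
  }
  if (!(pta$index %||% "auc_mic") %in% c("auc_mic", "cmax_mic", "t_above_mic"))
    .stopf("pta.index must be auc_mic, cmax_mic or t_above_mic")
  config
}

#' Validate (and default-fill) a configuration
#'
#' Checks the configuration schema before any computation: unknown keys are
#' rejected with their full path, every criterion endpoint must be resolvable
#' against the chosen structural model, CVs must be non-negative, and units
#' must be declared from the supported set.  Defaults (units, plan sizes,
#' criterion labels) are filled in and returned, so a validated
#' configuration is self-contained.
#'
#' @param config a nested configuration list (see [load_config()]).
#' @return The validated configuration with defaults materialised.
#' @export
validate_config <- function(config) {
  if (!is.list(config)) .stopf("configuration must be a list")
  if (!is.null(config$pta) && is.null(config$model))
    .validate_pta_config(config)
  else
    .validate_run_config(config)
}

#' Read a YAML configuration file
#'
#' @param path path to a YAML file describing a PoPS run (sections `model`,
#'   `uncertainty`, `criteria`, `plan`, optional `scenarios`) or a
#'   target-attainment run (section `pta`).
#' @return The validated configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) .stopf("configuration file not found: %s", path)
  validate_config(yaml::read_yaml(path))
}

.build_uncertainty <- function(config, model) {
  u <- config$uncertainty %||% list()
  fixed <- list()
  for (p in model$params) {
    fixed[[p]] <- if (!is.null(u$fixed[[p]]))
      as_dist(u$fixed[[p]])
    else if (!is.null(config$model$typical[[p]]))
      dist_point(config$model$typical[[p]])
    else
      .stopf("no value or distribution for parameter '%s'", p)
  }
  correlation <- NULL
  if (!is.null(u$correlation)) {
    cm <- u$correlation
    correlation <- matrix(unlist(cm$matrix), length(cm$params),
                          length(cm$params), byrow = TRUE,
                          dimnames = list(cm$params, cm$params))
  }
  bsv <- NULL
  if (!is.null(u$bsv)) {
    bcorr <- NULL
    if (!is.null(u$bsv$correlation)) {
      bc <- u$bsv$correlation
      bcorr <- matrix(unlist(bc$matrix), length(bc$params),
                      length(bc$params), byrow = TRUE,
                      dimnames = list(bc$params, bc$params))
    }
    bsv <- bsv_spec(cv = u$bsv$cv, correlation = bcorr,
                    scale = unlist(u$bsv$scale %||% "lognormal"))
  }
  list(fixed = fixed, correlation = correlation, bsv = bsv)
}

.build_criteria <- function(config) {
  crits <- lapply(names(config$criteria), function(lab) {
    cr <- config$criteria[[lab]]
    criterion(endpoint = cr$endpoint, comparator = cr$comparator,
              threshold = as_dist(cr$threshold),
              required_proportion = as_dist(cr$required_proportion),
              kind = cr$kind %||% "benefit",
              label = cr$label %||% lab,
              boundary = cr$boundary)
  })
  criteria_set(crits)
}

.build_plan <- function(config) {
  pl <- config$plan
  simulation_plan(doses = pl$doses, M = pl$M, N = pl$N, seed = pl$seed,
                  tau = pl$tau, route = pl$route, n_doses = pl$n_doses,
                  common_rng = pl$common_rng)
}

#' Run a PoPS configuration end to end
#'
#' Validates the configuration, assembles the structural model, uncertainty
#' specs, criteria and plan, and calls [compute_pops()].  Fixed-effect draw
#' order is the model's canonical parameter order, so equivalent YAML files
#' with re-ordered keys produce identical results.
#'
#' @param config a configuration list (e.g. from [load_config()] or a
#'   `make_case*_config()` fixture).
#' @param verbose passed to [compute_pops()].
#' @return A `pops_curve`.
#' @export
run_config <- function(config, verbose = FALSE) {
  config <- validate_config(config)
  model <- .build_model(config)
  compute_pops(.build_plan(config), model, .build_criteria(config),
               .build_uncertainty(config, model), verbose = verbose)
}

#' Modify a configuration by dotted path
#'
#' Assigns `value` at a dotted path such as
#' `"criteria.pharmacology.threshold"` or `"uncertainty.bsv.cv.Emax"`.
#' Used by [scenario_analysis()] to express scenario axes as named
#' assumptions.
#'
#' @param config a configuration list.
#' @param path dotted key path; every element must already exist.
#' @param value replacement value.
#' @return The modified configuration.
#' @export
set_config_path <- function(config, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1L]]
  rec <- function(node, keys) {
    k <- keys[1L]
    idx <- match(k, names(node))
    if (is.na(idx))
      .stopf("unknown configuration path element '%s' (in '%s')", k, path)
    if (length(keys) == 1L) node[[idx]] <- value
    else node[[idx]] <- rec(node[[idx]], keys[-1L])
    node
  }
  rec(config, keys)
}

get_config_path <- function(config, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1L]]
  node <- config
  for (k in keys) {
    idx <- match(k, names(node))
    if (is.na(idx))
      .stopf("unknown configuration path element '%s' (in '%s')", k, path)
    node <- node[[idx]]
  }
  node
}
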