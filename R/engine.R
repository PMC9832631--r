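# The nested Monte Carlo PoPS estimator: M outer uncertainty replicates
# (virtual trials) x N inner subjects per dose.

#' Simulation plan
#'
#' @param doses strictly increasing dose grid (amounts per administration).
#' @param M outer replicate (virtual trial) count, >= 1.  Default 500.
#' @param N subjects per replicate, >= 1.  Default 1000.
#' @param seed master seed; all randomness derives from it through
#'   [pops_substream()].
#' @param tau dosing interval.
#' @param route `"oral"` or `"iv-bolus"`.
#' @param n_doses administrations per subject.
#' @param common_rng reuse the same parameter, criteria and subject draws
#'   across doses (common random numbers; default `TRUE`).  This yields
#'   smooth PoPS-versus-dose curves in which differences between doses
#'   reflect the doses, not sampling noise.
#' @return Object of class `pops_plan`.
#' @export
simulation_plan <- function(doses, M = 500L, N = 1000L, seed = 1L,
                            tau = 24, route = "oral", n_doses = 1L,
                            common_rng = TRUE) {
  if (length(doses) == 0L || any(doses < 0) ||
      is.unsorted(doses, strictly = TRUE))
    .stopf("'doses' must be a non-empty, strictly increasing grid of non-negative doses")
  .assert_scalar_num(M, "M", 1)
  .assert_scalar_num(N, "N", 1)
  structure(list(doses = as.numeric(doses), M = as.integer(M),
                 N = as.integer(N), seed = seed, tau = tau, route = route,
                 n_doses = as.integer(n_doses),
                 common_rng = isTRUE(common_rng)),
            class = "pops_plan")
}

#' Endpoint model
#'
#' Wraps a structural model as a vectorised function from per-subject
#' parameters and a regimen to named per-subject endpoints.  `fn` receives a
#' numeric matrix (one row per subject, columns named by `params`), the
#' [regimen()], and an optional covariate matrix, and must return a numeric
#' matrix with one row per subject and columns named exactly `endpoints`.
#'
#' @param name model name (used in messages and result metadata).
#' @param params character vector of required parameter names.
#' @param endpoints character vector of output endpoint names.
#' @param fn `function(params_matrix, regimen, covariates)`.
#' @param covariates optional named list of [dist_spec()]s sampled
#'   per subject and passed to `fn` as a matrix (extension point; the
#'   bundled case configurations do not use it).
#' @return Object of class `pops_endpoint_model`.
#' @export
endpoint_model <- function(name, params, endpoints, fn, covariates = NULL) {
  stopifnot(is.character(params), is.character(endpoints), is.function(fn))
  structure(list(name = name, params = params, endpoints = endpoints,
                 fn = fn, covariates = covariates),
            class = "pops_endpoint_model")
}

# Per-subject parameter matrix: typical values perturbed by eta on the
# configured scale (lognormal: theta * exp(eta); normal: theta + eta).
.individual_params <- function(model, theta, bsv, etas, N) {
  P <- matrix(rep(theta[model$params], each = N), N,
              length(model$params),
              dimnames = list(NULL, model$params))
  for (p in colnames(etas)) {
    P[, p] <- if (.bsv_scale_for(bsv, p) == "lognormal")
      theta[[p]] * exp(etas[, p])
    else
      theta[[p]] + etas[, p]
  }
  P
}

.run_model <- function(model, P, reg, covariates = NULL) {
  em <- tryCatch(model$fn(P, reg, covariates), error = function(e)
    .stopf("structural model '%s' failed at dose %g: %s",
           model$name, reg$dose, conditionMessage(e)))
  if (anyNA(em)) {
    bad <- which(rowSums(is.na(em)) > 0)[1L]
    .stopf("structural model '%s' produced missing endpoints for subject %d (parameters: %s)",
           model$name, bad,
           paste(colnames(P), format(P[bad, ], digits = 6),
                 sep = "=", collapse = ", "))
  }
  em
}

#' Simulate one virtual population
#'
#' Builds per-subject parameters from the typical values `theta` and
#' subject-level random effects, runs the structural model, and returns the
#' endpoint matrix (one row per subject).  With an all-zero (or absent) BSV
#' spec all rows are identical.
#'
#' @param model an [endpoint_model()].
#' @param reg a [regimen()].
#' @param theta named typical parameter values (one outer-replicate draw).
#' @param bsv a [bsv_spec()] or `NULL`.
#' @param N number of subjects.
#' @param etas optional pre-drawn random-effect matrix (`N` rows, columns
#'   named by BSV parameter); drawn internally when omitted.
#' @param seed optional isolated seed for the internal eta draw.
#' @return `N x length(model$endpoints)` endpoint matrix.
#' @export
simulate_population <- function(model, reg, theta, bsv = NULL, N,
                                etas = NULL, seed = NULL) {
  if (is.null(etas)) {
    omega <- bsv_omega(bsv, theta = theta)
    etas <- draw_subject_etas(omega, N, seed = seed)
  }
  P <- .individual_params(model, theta, bsv, etas, N)
  .run_model(model, P, reg)
}

# All stochastic draws for one outer replicate.  Substream (i, k0): fixed
# effects (spec order, correlated block first), then BSV CV realisations,
# then criteria (K before n, set order).  Substream (i, k0+1): the subject
# eta matrix, then covariates.
.replicate_draws <- function(seed, i, k0, specs, corr_info, bsv, criteria,
                             model, N) {
  main <- withr::with_seed(pops_substream(seed, i, k0), {
    theta <- .draw_fixed_one(specs, corr_info)
    cv <- realize_bsv(bsv)
    crit <- realize_criteria(criteria)
    list(theta = theta, cv = cv, crit = crit)
  })
  omega <- if (length(main$cv))
    bsv_omega(bsv, main$cv, main$theta) else matrix(0, 0, 0)
  sub <- withr::with_seed(pops_substream(seed, i, k0 + 1L), {
    etas <- .draw_etas(omega, N)
    covs <- if (length(model$covariates))
      vapply(model$covariates, dist_sample, numeric(N), n = N)
    list(etas = etas, covs = covs)
  })
  list(theta = main$theta, crit = main$crit, etas = sub$etas,
       covariates = sub$covs)
}

#' Compute a PoPS-versus-dose curve
#'
#' The nested Monte Carlo estimator.  For each of `plan$M` outer replicates
#' it draws a full set of uncertain quantities — fixed effects (including
#' translation factors), BSV magnitudes, and criteria realisations
#' `(K_i, n_i)` — simulates `plan$N` subjects, evaluates the criteria set on
#' each dose, and reports `PoPS = M'/M`, the fraction of replicates in which
#' all criteria pass jointly.  Per-criterion pass rates and the median and
#' 90% band of the replicate-level subject proportions are reported
#' alongside.
#'
#' @section Reproducibility:
#' Replicate `i` draws from substream `pops_substream(seed, i, 0)` in the
#' order: fixed effects (declared spec order, any correlated block first),
#' BSV CVs with uncertain magnitude, criteria realisations (set order, `K`
#' before `n`); subject random effects come from substream `(i, 1)`.  Under
#' common random numbers (the default) the same draws are reused across the
#' dose grid, matching the practice of assigning one realisation of the
#' uncertain quantities to each simulated trial; with
#' `common_rng = FALSE` dose `d` uses substreams `(i, 2d)` and
#' `(i, 2d + 1)`.
#'
#' @param plan a [simulation_plan()].
#' @param model an [endpoint_model()].
#' @param criteria a [criteria_set()].
#' @param uncertainty list with elements `fixed` (named list of
#'   [dist_spec()]s covering every model parameter), optional `correlation`
#'   (named matrix over a subset of normal/log-normal parameters), and
#'   optional `bsv` (a [bsv_spec()]).
#' @param verbose emit a progress line every 100 replicates with the running
#'   PoPS estimate at the first dose.
#' @return A `pops_curve`: a data frame with one row per dose and columns
#'   `dose`, `pops`, and per criterion `pass_rate_<label>`,
#'   `prop_median_<label>`, `prop_lo_<label>`, `prop_hi_<label>`; the plan,
#'   criteria labels and a per-replicate diagnostic table are attached as
#'   attributes.
#' @seealso [optimal_dose()], [proportion_bands()], [scenario_analysis()]
#' @export
compute_pops <- function(plan, model, criteria, uncertainty = list(),
                         verbose = FALSE) {
  stopifnot(inherits(plan, "pops_plan"),
            inherits(model, "pops_endpoint_model"),
            inherits(criteria, "pops_criteria"))
  specs <- lapply(uncertainty$fixed %||% list(), as_dist)
  missing_p <- setdiff(model$params, names(specs))
  if (length(missing_p))
    .stopf("no distribution (or typical value) supplied for parameter(s): %s",
           paste(missing_p, collapse = ", "))
  corr_info <- .prep_correlation(specs, uncertainty$correlation)
  bsv <- uncertainty$bsv
  if (!is.null(bsv)) {
    if (!inherits(bsv, "pops_bsv")) .stopf("'uncertainty$bsv' must be a bsv_spec()")
    extra <- setdiff(names(bsv$cv), model$params)
    if (length(extra))
      .stopf("BSV declared for unknown parameter(s): %s",
             paste(extra, collapse = ", "))
  }
  D <- length(plan$doses); C <- length(criteria); M <- plan$M
  labs <- vapply(criteria, `[[`, "", "label")
  regs <- lapply(plan$doses, function(d)
    regimen(d, plan$tau, plan$route, plan$n_doses))
  pass <- matrix(NA, M, D)
  cpass <- array(NA, c(M, D, C))
  frac <- array(NA_real_, c(M, D, C))
  Ks <- array(NA_real_, c(M, D, C))
  ns <- array(NA_real_, c(M, D, C))
  for (i in seq_len(M)) {
    if (plan$common_rng)
      dr <- .replicate_draws(plan$seed, i, 0L, specs, corr_info, bsv,
                             criteria, model, plan$N)
    for (d in seq_len(D)) {
      if (!plan$common_rng)
        dr <- .replicate_draws(plan$seed, i, 2L * d, specs, corr_info, bsv,
                               criteria, model, plan$N)
      P <- .individual_params(model, dr$theta, bsv, dr$etas, plan$N)
      em <- .run_model(model, P, regs[[d]], dr$covariates)
      ev <- criteria_pass(dr$crit, em, criteria)
      pass[i, d] <- ev$pass
      cpass[i, d, ] <- ev$records$pass
      frac[i, d, ] <- ev$records$fraction
      Ks[i, d, ] <- ev$records$K
      ns[i, d, ] <- ev$records$n
    }
    if (verbose && i %% 100L == 0L)
      message(sprintf("replicate %d/%d: running PoPS at dose %g = %.3f",
                      i, M, plan$doses[1L], mean(pass[seq_len(i), 1L])))
  }
  out <- data.frame(dose = plan$doses, pops = colMeans(pass))
  for (j in seq_len(C)) {
    out[[paste0("pass_rate_", labs[j])]] <- colMeans(cpass[, , j, drop = FALSE])[, 1L]
    q <- apply(frac[, , j, drop = FALSE], 2L, quantile,
               probs = c(0.5, 0.05, 0.95), type = 7, names = FALSE)
    out[[paste0("prop_median_", labs[j])]] <- q[1L, ]
    out[[paste0("prop_lo_", labs[j])]] <- q[2L, ]
    out[[paste0("prop_hi_", labs[j])]] <- q[3L, ]
  }
  reps <- data.frame(
    replicate = rep(rep(seq_len(M), times = D), times = C),
    dose = rep(rep(plan$doses, each = M), times = C),
    criterion = rep(labs, each = M * D),
    K = as.vector(Ks), n = as.vector(ns),
    fraction = as.vector(frac), pass = as.vector(cpass),
    stringsAsFactors = FALSE)
  structure(out,
            class = c("pops_curve", "data.frame"),
            plan = plan, criteria_labels = labs, model_name = model$name,
            replicates = reps)
}

#' @export
print.pops_curve <- function(x, ...) {
  plan <- attr(x, "plan")
  cat(sprintf("PoPS curve (model '%s', M = %d trials x N = %d subjects, seed %s)\n",
              attr(x, "model_name"), plan$M, plan$N, format(plan$seed)))
  print.data.frame(x, digits = 4, row.names = FALSE)
  od <- optimal_dose(x)
  cat(sprintf("maximal PoPS %.3f at dose %g\n", od$pops, od$dose))
  invisible(x)
}

#' Median and predictive band of replicate-level proportions
#'
#' Type-7 (linear interpolation) percentiles of the per-replicate subject
#' proportions, as used for the bands around a proportion-versus-dose curve.
#'
#' @param fractions per-replicate proportions (one per virtual trial).
#' @param level band coverage (default 0.90: 5th to 95th percentile).
#' @return Named vector `median`, `lo`, `hi`.
#' @export
proportion_bands <- function(fractions, level = 0.90) {
  if (length(fractions) < 1L) .stopf("at least one replicate required")
  a <- (1 - level) / 2
  q <- quantile(fractions, probs = c(0.5, a, 1 - a), type = 7, names = FALSE)
  c(median = q[1L], lo = q[2L], hi = q[3L])
}

#' Dose with maximal PoPS
#'
#' Ties are broken towards the lowest dose.
#'
#' @param curve a `pops_curve`.
#' @return List with `dose` and `pops`.
#' @export
optimal_dose <- function(curve) {
  if (nrow(curve) == 0L) .stopf("empty curve")
  i <- which.max(curve$pops)
  list(dose = curve$dose[i], pops = curve$pops[i])
}
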