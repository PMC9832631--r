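# Uncertainty distributions: priors on fixed effects (d1), on BSV magnitude
# (d2), and on criteria thresholds / required proportions (d3, d4), plus the
# subject-level random effects eta ~ N(0, Omega).

.dist_families <- c("point", "normal", "lognormal", "uniform",
                    "scaled_beta", "weighted_categorical")

#' Uncertainty distribution specification
#'
#' An `UncertaintyDist` represents a prior on a fixed effect, a translation
#' factor, a criterion threshold, a required proportion, or a BSV magnitude.
#' Supported families:
#'
#' * `point` — degenerate; params `value`.
#' * `normal` — params `mean`, `sd` (`sd >= 0`).
#' * `lognormal` — params `meanlog`, `sdlog`, or the convenience pair
#'   `median`, `cv` (percent CV, converted via [cv_to_lognormal_sigma()]).
#' * `uniform` — params `lower < upper`.
#' * `scaled_beta` — a beta distribution rescaled to `[lower, upper]`,
#'   parameterised by its density `mode` and a `concentration` (> 2); see
#'   [scaled_beta()].
#' * `weighted_categorical` — discrete over `values` with non-negative
#'   `weights` (normalised internally); see [weighted_categorical()].
#'
#' @param family family name; `-` and `_` are interchangeable.
#' @param params named list of family-specific parameters.
#' @param units optional free-text unit label, carried for provenance.
#' @return An object of class `pops_dist`.
#' @seealso [dist_sample()], [as_dist()]
#' @examples
#' dist_spec("uniform", list(lower = 0.45, upper = 0.75), units = "unitless")
#' @export
dist_spec <- function(family, params, units = NULL) {
  if (!is.character(family) || length(family) != 1L)
    .stopf("distribution 'family' must be a single string")
  family <- gsub("-", "_", family, fixed = TRUE)
  if (!family %in% .dist_families)
    .stopf("unknown distribution family '%s' (known: %s)",
           family, paste(.dist_families, collapse = ", "))
  params <- as.list(params)
  p <- params
  switch(family,
    point = .assert_scalar_num(p$value, "value"),
    normal = {
      .assert_scalar_num(p$mean, "mean")
      .assert_scalar_num(p$sd, "sd", lower = 0)
    },
    lognormal = {
      if (!is.null(p$median) || !is.null(p$cv)) {
        .assert_scalar_num(p$median, "median", lower = 0, strict = TRUE)
        .assert_scalar_num(p$cv, "cv", lower = 0)
        params <- list(meanlog = log(p$median),
                       sdlog = cv_to_lognormal_sigma(p$cv))
      } else {
        .assert_scalar_num(p$meanlog, "meanlog")
        .assert_scalar_num(p$sdlog, "sdlog", lower = 0)
      }
    },
    uniform = {
      .assert_scalar_num(p$lower, "lower")
      .assert_scalar_num(p$upper, "upper")
      if (p$lower >= p$upper) .stopf("uniform requires lower < upper")
    },
    scaled_beta = {
      .assert_scalar_num(p$lower, "lower")
      .assert_scalar_num(p$upper, "upper")
      .assert_scalar_num(p$mode, "mode")
      if (p$lower >= p$upper) .stopf("scaled_beta requires lower < upper")
      if (p$mode < p$lower || p$mode > p$upper)
        .stopf("scaled_beta mode %g outside support [%g, %g]",
               p$mode, p$lower, p$upper)
      conc <- p$concentration %||% 4
      .assert_scalar_num(conc, "concentration", lower = 2, strict = TRUE)
      params$concentration <- conc
    },
    weighted_categorical = {
      v <- p$values; w <- p$weights
      if (length(v) != length(w) || length(v) == 0L)
        .stopf("weighted_categorical requires equal-length, non-empty 'values' and 'weights'")
      if (any(!is.finite(w)) || any(w < 0))
        .stopf("weighted_categorical weights must be non-negative")
      if (sum(w) <= 0)
        .stopf("weighted_categorical weights must sum to a positive number")
      params$values <- as.numeric(v)
      params$weights <- as.numeric(w)
    }
  )
  structure(list(family = family, params = params, units = units),
            class = "pops_dist")
}

#' @rdname dist_spec
#' @param value the single value of a point-mass distribution.
#' @export
dist_point <- function(value, units = NULL)
  dist_spec("point", list(value = value), units)

#' @rdname dist_spec
#' @param mean,sd normal location and scale.
#' @export
dist_normal <- function(mean, sd, units = NULL)
  dist_spec("normal", list(mean = mean, sd = sd), units)

#' @rdname dist_spec
#' @param meanlog,sdlog log-scale location and scale, or
#' @param median,cv positive median and percent CV (alternative
#'   parameterisation; `sdlog = cv_to_lognormal_sigma(cv)`).
#' @export
dist_lognormal <- function(meanlog = NULL, sdlog = NULL,
                           median = NULL, cv = NULL, units = NULL)
  dist_spec("lognormal",
            list(meanlog = meanlog, sdlog = sdlog, median = median, cv = cv),
            units)

#' @rdname dist_spec
#' @param lower,upper support bounds, `lower < upper`.
#' @export
dist_uniform <- function(lower, upper, units = NULL)
  dist_spec("uniform", list(lower = lower, upper = upper), units)

#' Scaled beta prior parameterised by mode and concentration
#'
#' A beta distribution rescaled from `[0, 1]` to `[lower, upper]`, with the
#' density mode placed at `mode`.  The shape parameters are recovered
#' analytically from the mode `m` (on the unit scale) and the concentration
#' `c = shape1 + shape2 > 2`: `shape1 = m (c - 2) + 1`,
#' `shape2 = (1 - m)(c - 2) + 1`.  With the mode near the lower bound the
#' density decreases monotonically towards the upper bound, which is the
#' intended shape for a pharmacology-need prior ("usually a small fold-change
#' suffices, occasionally much more is needed").
#'
#' @inheritParams dist_spec
#' @param mode density mode, within `[lower, upper]`.
#' @param lower,upper support bounds, `lower < upper`.
#' @param concentration total concentration `shape1 + shape2`; must be > 2.
#'   Larger values concentrate mass around the mode.  Default 4.
#' @return A `pops_dist` of family `scaled_beta`.
#' @examples
#' scaled_beta(mode = 2, lower = 1, upper = 16)
#' @export
scaled_beta <- function(mode, lower, upper, concentration = 4, units = NULL)
  dist_spec("scaled_beta",
            list(mode = mode, lower = lower, upper = upper,
                 concentration = concentration),
            units)

.beta_shapes <- function(p) {
  m <- (p$mode - p$lower) / (p$upper - p$lower)
  c(shape1 = m * (p$concentration - 2) + 1,
    shape2 = (1 - m) * (p$concentration - 2) + 1)
}

#' Weighted categorical prior
#'
#' A discrete prior drawing `values[k]` with probability
#' `weights[k] / sum(weights)`.  Used e.g. for a species-weighted safety
#' limit, where each candidate exposure limit carries a relevance weight.
#'
#' @inheritParams dist_spec
#' @param values numeric values to draw from.
#' @param weights non-negative weights, same length as `values`, positive sum.
#' @return A `pops_dist` of family `weighted_categorical`.
#' @examples
#' weighted_categorical(c(1.2, 2.0, 3.5), c(60, 30, 10))
#' @export
weighted_categorical <- function(values, weights, units = NULL)
  dist_spec("weighted_categorical",
            list(values = values, weights = weights), units)

#' Coerce to an uncertainty distribution
#'
#' Single numbers become point masses; lists with a `family` element are
#' passed to [dist_spec()]; `pops_dist` objects are returned unchanged.
#'
#' @param x a number, a list, or a `pops_dist`.
#' @return A `pops_dist`.
#' @export
as_dist <- function(x) {
  if (inherits(x, "pops_dist")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(dist_point(x))
  if (is.list(x) && !is.null(x$family))
    return(dist_spec(x$family, x$params %||% list(), x$units))
  .stopf("cannot interpret object of class '%s' as a distribution",
         paste(class(x), collapse = "/"))
}

#' Sample from an uncertainty distribution
#'
#' Point masses return their value without consuming random numbers, so that
#' replacing a prior by a point estimate leaves all other draws in a
#' replicate's substream unchanged.  Log-normal sampling is implemented as
#' `exp(rnorm(n, meanlog, sdlog))`, consuming exactly `n` standard normals.
#'
#' @param dist a `pops_dist` (or anything [as_dist()] accepts).
#' @param n number of draws.
#' @param seed optional seed; when given, sampling runs in an isolated RNG
#'   state (the caller's stream is untouched).
#' @return Numeric vector of length `n`.
#' @examples
#' dist_sample(dist_uniform(0.45, 0.75), 5, seed = 1)
#' @export
dist_sample <- function(dist, n, seed = NULL) {
  dist <- as_dist(dist)
  if (!is.null(seed))
    return(withr::with_seed(seed, dist_sample(dist, n)))
  p <- dist$params
  switch(dist$family,
    point = rep(p$value, n),
    normal = rnorm(n, p$mean, p$sd),
    lognormal = exp(rnorm(n, p$meanlog, p$sdlog)),
    uniform = runif(n, p$lower, p$upper),
    scaled_beta = {
      sh <- .beta_shapes(p)
      p$lower + (p$upper - p$lower) * rbeta(n, sh[["shape1"]], sh[["shape2"]])
    },
    weighted_categorical = {
      w <- p$weights / sum(p$weights)
      p$values[sample.int(length(p$values), n, replace = TRUE, prob = w)]
    })
}

#' @export
print.pops_dist <- function(x, ...) {
  ps <- vapply(x$params, function(v) paste(format(v, digits = 6), collapse = ","), "")
  cat(sprintf("<pops_dist %s(%s)%s>\n", x$family,
              paste(names(ps), ps, sep = "=", collapse = ", "),
              if (is.null(x$units)) "" else paste0(" [", x$units, "]")))
  invisible(x)
}

#' Convert a percent CV to a log-normal log-scale SD
#'
#' For a log-normal variable with coefficient of variation `cv` (percent),
#' the log-scale standard deviation is `sqrt(log(1 + (cv/100)^2))`.  This is
#' the convention used throughout for log-normal BSV: a typical value
#' perturbed as `theta * exp(eta)` keeps its median at `theta`.
#'
#' @param cv_percent percent coefficient of variation (>= 0).
#' @return Log-scale standard deviation.
#' @examples
#' cv_to_lognormal_sigma(30)  # 0.2936
#' @export
cv_to_lognormal_sigma <- function(cv_percent) {
  if (!is.numeric(cv_percent) || any(!is.finite(cv_percent)) || any(cv_percent < 0))
    .stopf("'cv_percent' must be non-negative and finite")
  sqrt(log(1 + (cv_percent / 100)^2))
}

# Validate a correlation matrix over a subset of fixed-effect specs and
# pre-compute its Cholesky factor.  Only normal / lognormal marginals can be
# coupled through the Gaussian dependence structure.
.prep_correlation <- function(specs, correlation) {
  if (is.null(correlation)) return(NULL)
  correlation <- as.matrix(correlation)
  nm <- colnames(correlation)
  if (is.null(nm) || !identical(nm, rownames(correlation)))
    .stopf("correlation matrix must have matching row/column names")
  unknown <- setdiff(nm, names(specs))
  if (length(unknown))
    .stopf("correlation names parameters without a distribution: %s",
           paste(unknown, collapse = ", "))
  fams <- vapply(specs[nm], function(s) as_dist(s)$family, "")
  bad <- nm[!fams %in% c("normal", "lognormal")]
  if (length(bad))
    .stopf("correlated parameters must be normal or log-normal; offending: %s",
           paste(bad, collapse = ", "))
  if (max(abs(correlation - t(correlation))) > 1e-10)
    .stopf("correlation matrix must be symmetric")
  if (max(abs(diag(correlation) - 1)) > 1e-10)
    .stopf("correlation matrix must have unit diagonal")
  ch <- tryCatch(chol(correlation), error = function(e)
    .stopf("correlation matrix is not positive definite"))
  list(params = nm, chol = ch)
}

# One joint draw of all fixed effects, in spec order.  The correlated block
# (if any) is drawn first from a single multivariate Gaussian; the remaining
# parameters follow independently in their declared order.
.draw_fixed_one <- function(specs, corr_info = NULL) {
  out <- setNames(numeric(length(specs)), names(specs))
  done <- character(0)
  if (!is.null(corr_info)) {
    k <- length(corr_info$params)
    z <- drop(matrix(rnorm(k), 1L, k) %*% corr_info$chol)
    for (j in seq_len(k)) {
      p <- corr_info$params[j]
      d <- as_dist(specs[[p]])
      out[p] <- if (d$family == "normal")
        d$params$mean + d$params$sd * z[j]
      else
        exp(d$params$meanlog + d$params$sdlog * z[j])
    }
    done <- corr_info$params
  }
  for (p in setdiff(names(specs), done))
    out[p] <- dist_sample(specs[[p]], 1L)
  out
}

#' Draw fixed-effect parameter sets for outer replicates
#'
#' Draws `M` independent realisations of the fixed effects (typical values,
#' translation factors, and any other per-replicate quantities) from their
#' uncertainty distributions.  Replicate `i` uses substream
#' `pops_substream(seed, i, 0)`, the same discipline [compute_pops()] uses,
#' so the `i`-th row here equals the fixed effects of engine replicate `i`
#' run with the same seed.
#'
#' Correlated parameters (normal or log-normal marginals only) are drawn
#' jointly on the (log-)scale through a Gaussian dependence structure; they
#' consume one block of standard normals before the remaining parameters are
#' drawn in declared order.
#'
#' @param specs named list of `pops_dist` (or coercible) specs, one per
#'   parameter; the declared order fixes the draw order.
#' @param correlation optional named correlation matrix over a subset of the
#'   parameters.
#' @param M number of replicates (>= 1).
#' @param seed master seed.
#' @return An `M x length(specs)` matrix, columns named by parameter.
#' @examples
#' draw_fixed_effects(list(kp_uu = dist_uniform(0.45, 0.75)), M = 3, seed = 1)
#' @export
draw_fixed_effects <- function(specs, correlation = NULL, M, seed) {
  if (!is.list(specs) || is.null(names(specs)) || any(names(specs) == ""))
    .stopf("'specs' must be a fully named list of distributions")
  .assert_scalar_num(M, "M", lower = 1)
  specs <- lapply(specs, as_dist)
  corr_info <- .prep_correlation(specs, correlation)
  out <- matrix(NA_real_, M, length(specs),
                dimnames = list(NULL, names(specs)))
  for (i in seq_len(M))
    out[i, ] <- withr::with_seed(pops_substream(seed, i, 0L),
                                 .draw_fixed_one(specs, corr_info))
  out
}

#' Between-subject variability specification
#'
#' Declares which parameters carry BSV, as percent CVs, with an optional
#' correlation matrix and the scale on which the random effect acts.  On the
#' default log-normal scale a subject's parameter is
#' `theta * exp(eta)` with `sd(eta) = cv_to_lognormal_sigma(cv)`; on the
#' normal scale it is `theta + eta` with `sd(eta) = cv/100 * |theta|`
#' (available for baselines that may be negative).  A CV may itself be an
#' uncertainty distribution (BSV magnitude uncertain), realised once per
#' outer replicate.
#'
#' @param cv named numeric vector or named list; each element a percent CV
#'   (>= 0) or a `pops_dist` over percent CVs.
#' @param correlation optional named correlation matrix over (a subset
#'   ordering of) the same parameters.
#' @param scale `"lognormal"` (default) or `"normal"`; either a single value
#'   for all parameters or a named vector with per-parameter overrides.
#' @return An object of class `pops_bsv`.
#' @examples
#' bsv_spec(cv = c(CL = 30, EC50 = 30))
#' @export
bsv_spec <- function(cv, correlation = NULL, scale = "lognormal") {
  cv <- as.list(cv)
  if (length(cv) && (is.null(names(cv)) || any(names(cv) == "")))
    .stopf("'cv' must be fully named")
  for (p in names(cv)) {
    v <- cv[[p]]
    if (is.numeric(v) && length(v) == 1L) {
      if (!is.finite(v) || v < 0) .stopf("BSV CV for '%s' must be >= 0", p)
    } else {
      cv[[p]] <- as_dist(v)
    }
  }
  if (!all(scale %in% c("lognormal", "normal")))
    .stopf("BSV scale must be 'lognormal' or 'normal'")
  if (!is.null(correlation)) {
    correlation <- as.matrix(correlation)
    nm <- colnames(correlation)
    if (is.null(nm) || !setequal(nm, names(cv)))
      .stopf("BSV correlation must be named over the same parameters as 'cv'")
    correlation <- correlation[names(cv), names(cv), drop = FALSE]
    if (max(abs(correlation - t(correlation))) > 1e-10 ||
        max(abs(diag(correlation) - 1)) > 1e-10)
      .stopf("BSV correlation must be symmetric with unit diagonal")
    ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
      .stopf("BSV correlation must be positive semidefinite")
  }
  structure(list(cv = cv, correlation = correlation, scale = scale),
            class = "pops_bsv")
}

.bsv_scale_for <- function(bsv, p) {
  s <- bsv$scale
  if (!is.null(names(s)) && p %in% names(s)) s[[p]] else s[[1L]]
}

# Realise the CV vector of a BSV spec (consumes RNG only for uncertain CVs).
realize_bsv <- function(bsv) {
  if (is.null(bsv)) return(numeric(0))
  vapply(names(bsv$cv), function(p) {
    v <- bsv$cv[[p]]
    if (inherits(v, "pops_dist")) dist_sample(v, 1L) else as.numeric(v)
  }, numeric(1))
}

#' Build a random-effect covariance matrix from a BSV spec
#'
#' @param bsv a [bsv_spec()].
#' @param cv_values realised percent CVs, named as in `bsv$cv` (e.g. from an
#'   outer-replicate draw); defaults to the point CVs in the spec.
#' @param theta named typical values; required when any parameter uses the
#'   normal scale (its SD is `cv/100 * |theta|`).
#' @return Covariance matrix of the subject-level random effects, with
#'   parameter dimnames.
#' @export
bsv_omega <- function(bsv, cv_values = NULL, theta = NULL) {
  if (is.null(bsv) || length(bsv$cv) == 0L)
    return(matrix(0, 0, 0))
  cv_values <- cv_values %||% realize_bsv(bsv)
  nm <- names(bsv$cv)
  sig <- vapply(nm, function(p) {
    if (.bsv_scale_for(bsv, p) == "lognormal")
      cv_to_lognormal_sigma(cv_values[[p]])
    else {
      if (is.null(theta) || is.null(theta[[p]]))
        .stopf("normal-scale BSV for '%s' needs the typical value", p)
      cv_values[[p]] / 100 * abs(theta[[p]])
    }
  }, numeric(1))
  corr <- bsv$correlation %||% diag(length(nm))
  omega <- outer(sig, sig) * corr
  dimnames(omega) <- list(nm, nm)
  omega
}

# Internal eta sampler operating on the current RNG state.  Uses the upper
# Cholesky factor when omega is positive definite and an eigen square root
# for semidefinite matrices (zero-variance components stay exactly zero).
.draw_etas <- function(omega, N) {
  k <- ncol(omega)
  if (k == 0L) return(matrix(0, N, 0L))
  if (all(omega == 0))
    return(matrix(0, N, k, dimnames = list(NULL, colnames(omega))))
  ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev)))
    .stopf("omega is not positive semidefinite:\n%s",
           paste(utils::capture.output(print(omega)), collapse = "\n"))
  Z <- matrix(rnorm(N * k), N, k)
  L <- tryCatch(chol(omega), error = function(e) NULL)
  E <- if (!is.null(L)) Z %*% L else {
    es <- eigen(omega, symmetric = TRUE)
    Z %*% (diag(sqrt(pmax(es$values, 0)), k) %*% t(es$vectors))
  }
  colnames(E) <- colnames(omega)
  E
}

#' Draw subject-level random effects
#'
#' `N` multivariate normal draws with zero mean and covariance `omega`.
#' An all-zero `omega` returns exact zeros; a matrix with negative
#' eigenvalues beyond numerical tolerance is rejected with the matrix echoed
#' in the error message.
#'
#' @param omega positive semidefinite covariance matrix (may be `0 x 0`).
#' @param N number of subjects (>= 1).
#' @param seed optional isolated seed (see [dist_sample()]).
#' @return `N x ncol(omega)` matrix of random effects.
#' @examples
#' draw_subject_etas(matrix(0.09, 1, 1), N = 4, seed = 1)
#' @export
draw_subject_etas <- function(omega, N, seed = NULL) {
  omega <- as.matrix(omega)
  if (nrow(omega) != ncol(omega)) .stopf("omega must be square")
  .assert_scalar_num(N, "N", lower = 1)
  if (!is.null(seed))
    return(withr::with_seed(seed, .draw_etas(omega, N)))
  .draw_etas(omega, N)
}
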