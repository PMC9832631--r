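# Closed-form exposure and exposure-response building blocks.

#' Dosing regimen
#'
#' @param dose dose amount per administration (mg), >= 0.
#' @param tau dosing interval (time units of the model, typically h), > 0.
#' @param route `"oral"` or `"iv-bolus"`.  For oral dosing, relative
#'   bioavailability is folded into the apparent parameters (CL/F, V/F).
#' @param n_doses number of administrations (>= 1).
#' @return An object of class `pops_regimen`.
#' @examples
#' regimen(240, tau = 24)
#' @export
regimen <- function(dose, tau = 24, route = c("oral", "iv-bolus"),
                    n_doses = 1L) {
  route <- match.arg(route)
  .assert_scalar_num(dose, "dose", lower = 0)
  .assert_scalar_num(tau, "tau", lower = 0, strict = TRUE)
  .assert_scalar_num(n_doses, "n_doses", lower = 1)
  structure(list(dose = dose, tau = tau, route = route,
                 n_doses = as.integer(n_doses)),
            class = "pops_regimen")
}

#' Steady-state average concentration
#'
#' `Css,avg = dose / (CL/F * tau)`, the average total concentration over one
#' dosing interval at steady state for linear elimination; independent of
#' route and absorption rate.  Free-fraction and partition corrections are
#' applied separately via [site_free_concentration()].
#'
#' @param reg a [regimen()].
#' @param cl_over_f apparent clearance (L per time unit), > 0; may be a
#'   vector (e.g. per-subject clearances).
#' @return Average steady-state concentration (dose unit / L).
#' @examples
#' css_average(regimen(240, tau = 24), cl_over_f = 10)  # 1 mg/L
#' @export
css_average <- function(reg, cl_over_f) {
  if (any(cl_over_f <= 0)) .stopf("'cl_over_f' must be > 0")
  reg$dose / (cl_over_f * reg$tau)
}

#' Steady-state average concentration with Michaelis-Menten elimination
#'
#' Average steady-state concentration when elimination has a linear component
#' `CL * C` and a saturable component `Vmax * C / (Km + C)` (the
#' quasi-steady-state reduction of target-mediated disposition).  At steady
#' state the dosing rate `dose/tau` balances total elimination, giving a
#' quadratic in `C` whose positive root is returned.
#'
#' @param reg a [regimen()].
#' @param cl linear clearance (L/time), > 0; vectorised over subjects.
#' @param vmax maximal saturable elimination rate (amount/time), >= 0.
#' @param km concentration of half-maximal saturable elimination, > 0.
#' @return Steady-state average concentration.
#' @export
css_average_mm <- function(reg, cl, vmax, km) {
  if (any(cl <= 0)) .stopf("'cl' must be > 0")
  if (any(vmax < 0)) .stopf("'vmax' must be >= 0")
  if (any(km <= 0)) .stopf("'km' must be > 0")
  rate <- reg$dose / reg$tau
  b <- cl * km + vmax - rate
  (-b + sqrt(b^2 + 4 * cl * rate * km)) / (2 * cl)
}

#' One-compartment concentration-time profile
#'
#' Analytic superposition of `n_doses` administrations every `tau` for a
#' one-compartment model with first-order elimination and, for oral dosing,
#' first-order absorption.  The degenerate case `ka == ke` uses the limiting
#' form `(D/V) * ka * t * exp(-ka t)` rather than failing.
#'
#' @param params list with `cl` (clearance), `v` (volume) and, for oral
#'   dosing, `ka` (absorption rate constant), all > 0.
#' @param reg a [regimen()].
#' @param times non-negative, non-decreasing time grid.
#' @return Numeric vector of total concentrations at `times`.
#' @examples
#' conc_profile_onecomp(list(cl = 10, v = 50, ka = 1),
#'                      regimen(100, 24, "oral", 3), times = 0:72)
#' @export
conc_profile_onecomp <- function(params, reg, times) {
  if (any(times < 0) || is.unsorted(times))
    .stopf("'times' must be non-negative and non-decreasing")
  cl <- params$cl; v <- params$v
  .assert_scalar_num(cl, "cl", lower = 0, strict = TRUE)
  .assert_scalar_num(v, "v", lower = 0, strict = TRUE)
  ke <- cl / v
  one <- if (reg$route == "iv-bolus") {
    function(s) ifelse(s < 0, 0, reg$dose / v * exp(-ke * s))
  } else {
    ka <- params$ka
    .assert_scalar_num(ka, "ka", lower = 0, strict = TRUE)
    if (abs(ka - ke) < 1e-8 * ke) {
      function(s) ifelse(s < 0, 0, reg$dose / v * ka * s * exp(-ka * s))
    } else {
      function(s) ifelse(s < 0, 0,
        reg$dose / v * ka / (ka - ke) * (exp(-ke * s) - exp(-ka * s)))
    }
  }
  conc <- numeric(length(times))
  for (k in seq_len(reg$n_doses) - 1L)
    conc <- conc + one(times - k * reg$tau)
  pmax(conc, 0)
}

#' Translate plasma total concentration to a site-specific concentration
#'
#' * `plasma`: free plasma concentration `C * fu`;
#' * `brain`: free brain concentration `C * fu * kp_uu` (unbound
#'   brain-to-plasma partition coefficient);
#' * `tissue`: total tissue concentration `C * kp_tissue` (plasma-to-tissue
#'   distribution coefficient).
#'
#' @param c_plasma_total total plasma concentration(s), >= 0.
#' @param partition list with `fu` (unbound fraction in (0, 1]), `kp_uu`
#'   (> 0) and/or `kp_tissue` (> 0), as required by `site`.
#' @param site one of `"plasma"`, `"brain"`, `"tissue"`.
#' @return Concentration(s) at the requested site.
#' @examples
#' site_free_concentration(10, list(fu = 0.1, kp_uu = 0.5), "brain")  # 0.5
#' @export
site_free_concentration <- function(c_plasma_total, partition,
                                    site = c("plasma", "brain", "tissue")) {
  site <- match.arg(site)
  if (any(c_plasma_total < 0)) .stopf("concentrations must be >= 0")
  need <- switch(site, plasma = "fu", brain = c("fu", "kp_uu"),
                 tissue = "kp_tissue")
  miss <- need[vapply(need, function(p) is.null(partition[[p]]), TRUE)]
  if (length(miss))
    .stopf("configuration error: partition parameter(s) %s required for site '%s'",
           paste(miss, collapse = ", "), site)
  if (!is.null(partition$fu) &&
      (partition$fu <= 0 || partition$fu > 1))
    .stopf("'fu' must be in (0, 1]")
  switch(site,
    plasma = c_plasma_total * partition$fu,
    brain = c_plasma_total * partition$fu * partition$kp_uu,
    tissue = c_plasma_total * partition$kp_tissue)
}

#' Sigmoidal maximum-effect model and its inverse
#'
#' `emax_effect()` computes `Emax * C^h / (EC50^h + C^h)`;
#' `emax_inverse()` solves for the concentration producing a given effect,
#' `EC50 * (E / (Emax - E))^(1/h)`, and round-trips with `emax_effect()` to
#' better than 1e-9 on `(0, Emax)`.
#'
#' @param c concentration(s), >= 0.
#' @param p list with `emax` (>= 0), `ec50` (> 0) and optional `hill`
#'   (> 0, default 1).
#' @return Effect(s) in `[0, Emax)`.
#' @examples
#' emax_effect(9, list(emax = 1, ec50 = 1))   # 0.9
#' emax_inverse(0.9, list(emax = 1, ec50 = 1)) # 9
#' @export
emax_effect <- function(c, p) {
  if (any(c < 0)) .stopf("concentrations must be >= 0")
  h <- p$hill %||% 1
  if (p$ec50 <= 0 || h <= 0 || p$emax < 0)
    .stopf("invalid Emax parameters (need emax >= 0, ec50 > 0, hill > 0)")
  p$emax * c^h / (p$ec50^h + c^h)
}

#' @rdname emax_effect
#' @param effect effect(s), each in `[0, Emax)`; values at or above `Emax`
#'   are unreachable and rejected.
#' @export
emax_inverse <- function(effect, p) {
  h <- p$hill %||% 1
  if (any(effect < 0) || any(effect >= p$emax))
    .stopf("'effect' must be within [0, Emax); Emax = %g", p$emax)
  p$ec50 * (effect / (p$emax - effect))^(1 / h)
}

#' Required central inhibition to normalise an elevated target
#'
#' If disease elevates target activity `fold`-fold, the fractional inhibition
#' that brings `fold * (1 - I)` back to the normal level is `1 - 1/fold`.
#'
#' @param fold_elevation fold elevation of target activity, >= 1.
#' @return Required inhibition fraction in `[0, 1)`.
#' @examples
#' required_central_inhibition(2)  # 0.5
#' @export
required_central_inhibition <- function(fold_elevation) {
  if (any(fold_elevation < 1)) .stopf("'fold_elevation' must be >= 1")
  1 - 1 / fold_elevation
}

#' Allometric scaling specification and transform
#'
#' `allometric_scale()` scales a parameter between body weights as
#' `value * (to/from)^exponent`, with the conventional exponents 0.75 for
#' clearance-like and 1.0 for volume-like parameters.  The spec also carries
#' a baseline-scaling factor for cross-species adjustment of baseline target
#' levels.
#'
#' @param reference_weight reference body weight (kg), > 0.
#' @param exponents named numeric vector with `clearance` and `volume`
#'   exponents.
#' @param baseline_scaling multiplicative cross-species factor for baseline
#'   target level (default 1).
#' @return `allometric_spec()` returns a list of class `pops_allometry`;
#'   `allometric_scale()` returns the scaled parameter value.
#' @examples
#' allometric_scale(1, "clearance", from_weight = 3, to_weight = 70)  # ~10.6
#' @export
allometric_spec <- function(reference_weight = 70,
                            exponents = c(clearance = 0.75, volume = 1.0),
                            baseline_scaling = 1) {
  .assert_scalar_num(reference_weight, "reference_weight", 0, strict = TRUE)
  structure(list(reference_weight = reference_weight,
                 exponents = exponents,
                 baseline_scaling = baseline_scaling),
            class = "pops_allometry")
}

#' @rdname allometric_spec
#' @param value parameter value at `from_weight`.
#' @param kind `"clearance"` or `"volume"` (selects the exponent).
#' @param from_weight,to_weight body weights (kg), > 0.
#' @param spec an [allometric_spec()].
#' @export
allometric_scale <- function(value, kind = c("clearance", "volume"),
                             from_weight, to_weight,
                             spec = allometric_spec()) {
  kind <- match.arg(kind)
  .assert_scalar_num(from_weight, "from_weight", 0, strict = TRUE)
  .assert_scalar_num(to_weight, "to_weight", 0, strict = TRUE)
  value * (to_weight / from_weight)^spec$exponents[[kind]]
}

#' Trapezoidal area under a concentration-time curve
#'
#' Linear-trapezoid AUC over `[t0, t1]`, with linear interpolation of the
#' profile at the interval ends when they fall between grid points.
#'
#' @param times time grid (strictly increasing).
#' @param conc concentrations at `times`.
#' @param t0,t1 integration limits, within the grid span, `t1 > t0`.
#' @return Area (concentration x time).
#' @examples
#' auc_interval(0:24, rep(2, 25), 0, 24)  # 48
#' @export
auc_interval <- function(times, conc, t0 = min(times), t1 = max(times)) {
  if (length(times) != length(conc) || length(times) < 2L)
    .stopf("'times' and 'conc' must have equal length >= 2")
  if (is.unsorted(times, strictly = TRUE))
    .stopf("'times' must be strictly increasing")
  if (t1 <= t0) .stopf("'t1' must be > 't0'")
  if (t0 < min(times) || t1 > max(times))
    .stopf("[t0, t1] must lie within the time grid span")
  keep <- times > t0 & times < t1
  tt <- c(t0, times[keep], t1)
  cc <- c(approx(times, conc, t0)$y, conc[keep], approx(times, conc, t1)$y)
  sum(diff(tt) * (head2(cc) + cc[-1]) / 2)
}

head2 <- function(x) x[-length(x)]
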