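# ODE-based exposure-response models: turnover (indirect response /
# transduction chain) and target-mediated drug disposition.

#' Turnover (indirect response) model parameters
#'
#' A response produced at rate `kin` and lost at first-order rate `kout`
#' (baseline `R0 = kin/kout`), with drug modulating one of the two rates
#' through a saturable effect `E(C)`.  An optional transit chain (rate
#' `kout` per step) delays the observed response, covering
#' transduction-type models that translate an ex vivo concentration-response
#' into an in vivo biomarker time course.
#'
#' @param kin production rate (response/time), > 0.
#' @param kout first-order loss rate (1/time), > 0.
#' @param mode one of `"inhibit-production"`, `"stimulate-production"`,
#'   `"inhibit-loss"`, `"stimulate-loss"`.
#' @param effect drug-effect parameters for [emax_effect()]:
#'   list with `emax`, `ec50`, optional `hill`.
#' @param n_transit number of transit compartments (>= 0, default 0).
#' @return List of class `pops_turnover`.
#' @export
turnover_params <- function(kin, kout,
                            mode = c("inhibit-production",
                                     "stimulate-production",
                                     "inhibit-loss", "stimulate-loss"),
                            effect, n_transit = 0L) {
  mode <- match.arg(mode)
  .assert_scalar_num(kin, "kin", 0, strict = TRUE)
  .assert_scalar_num(kout, "kout", 0, strict = TRUE)
  .assert_scalar_num(n_transit, "n_transit", 0)
  structure(list(kin = kin, kout = kout, mode = mode, effect = effect,
                 n_transit = as.integer(n_transit), r0 = kin / kout),
            class = "pops_turnover")
}

#' Simulate a turnover response profile
#'
#' Numerically integrates the turnover ODE driven by a concentration
#' function.  All compartments start at the baseline `R0 = kin/kout`, so
#' with zero drug the response stays flat at baseline (within solver
#' tolerance).
#'
#' @param p a [turnover_params()].
#' @param conc_at function of time returning the driving concentration.
#' @param times non-decreasing time grid.
#' @param rtol,atol solver tolerances (defaults 1e-8 / 1e-10).
#' @return `data.frame(time, response)`; `response` is the last compartment
#'   of the transit chain (the observed response).
#' @seealso [turnover_steady_state()] for the constant-concentration
#'   analytic steady state.
#' @export
turnover_profile <- function(p, conc_at, times, rtol = 1e-8, atol = 1e-10) {
  if (is.unsorted(times)) .stopf("'times' must be non-decreasing")
  nst <- 1L + p$n_transit
  y0 <- rep(p$r0, nst)
  deriv <- function(t, y, parms) {
    E <- emax_effect(conc_at(t), p$effect)
    dR <- switch(p$mode,
      `inhibit-production` = p$kin * (1 - E) - p$kout * y[1],
      `stimulate-production` = p$kin * (1 + E) - p$kout * y[1],
      `inhibit-loss` = p$kin - p$kout * (1 - E) * y[1],
      `stimulate-loss` = p$kin - p$kout * (1 + E) * y[1])
    d <- c(dR, if (nst > 1L) p$kout * (y[-nst] - y[-1L]))
    list(d)
  }
  sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                      rtol = rtol, atol = atol)
  if (anyNA(sol))
    .stopf("turnover ODE solver failed (kin=%g, kout=%g, mode=%s)",
           p$kin, p$kout, p$mode)
  data.frame(time = sol[, 1L], response = sol[, nst + 1L])
}

#' Analytic turnover steady state at constant concentration
#'
#' Closed-form steady state of the turnover model under a constant driving
#' concentration: `R0 (1 - E)` / `R0 (1 + E)` for production modulation and
#' `R0 / (1 - E)` / `R0 / (1 + E)` for loss modulation, with
#' `E = emax_effect(conc, p$effect)`.
#'
#' @param p a [turnover_params()].
#' @param conc constant concentration(s), >= 0.
#' @return Steady-state response.
#' @export
turnover_steady_state <- function(p, conc) {
  E <- emax_effect(conc, p$effect)
  switch(p$mode,
    `inhibit-production` = p$r0 * (1 - E),
    `stimulate-production` = p$r0 * (1 + E),
    `inhibit-loss` = p$r0 / (1 - E),
    `stimulate-loss` = p$r0 / (1 + E))
}

#' Target-mediated drug disposition model parameters
#'
#' Two-compartment linear PK plus a synthesised/degraded target that binds
#' drug; the complex is internalised at rate `kint`.  Binding is specified
#' either microscopically as `(kon, koff)` for the full model or via the
#' quasi-steady-state constant `kss = (koff + kint)/kon`.  The baseline free
#' target is `r0 = ksyn/kdeg`; supplying both `ksyn` and `r0` requires them
#' to be consistent.
#'
#' @param cl,v1,q,v2 linear two-compartment parameters (> 0): central
#'   clearance, central volume, inter-compartment clearance, peripheral
#'   volume.
#' @param kdeg target degradation rate (1/time), > 0.
#' @param kint complex internalisation rate (1/time), > 0.
#' @param ksyn target synthesis rate (concentration/time); `>= 0` (zero
#'   target reduces the model to linear PK).  Derived from `r0 * kdeg` if
#'   omitted.
#' @param r0 baseline free target concentration; derived from `ksyn/kdeg`
#'   if omitted.
#' @param kon,koff association / dissociation rates (full model).
#' @param kss quasi-steady-state binding constant.
#' @return List of class `pops_tmdd`.
#' @export
tmdd_params <- function(cl, v1, q, v2, kdeg, kint,
                        ksyn = NULL, r0 = NULL,
                        kon = NULL, koff = NULL, kss = NULL) {
  for (nm in c("cl", "v1", "q", "v2", "kdeg", "kint"))
    .assert_scalar_num(get(nm), nm, 0, strict = TRUE)
  if (is.null(ksyn) && is.null(r0))
    .stopf("one of 'ksyn' or 'r0' is required (use 0 for no target)")
  if (is.null(ksyn)) ksyn <- r0 * kdeg
  if (is.null(r0)) r0 <- ksyn / kdeg
  if (abs(r0 * kdeg - ksyn) > 1e-8 * max(ksyn, kdeg, 1))
    .stopf("inconsistent baseline: r0 (%g) != ksyn/kdeg (%g)",
           r0, ksyn / kdeg)
  if (is.null(kss)) {
    if (is.null(kon) || is.null(koff))
      .stopf("binding must be given as (kon, koff) or as kss")
    kss <- (koff + kint) / kon
  }
  structure(list(cl = cl, v1 = v1, q = q, v2 = v2, ksyn = ksyn,
                 kdeg = kdeg, kint = kint, kon = kon, koff = koff,
                 kss = kss, r0 = r0),
            class = "pops_tmdd")
}

#' Simulate a target-mediated drug disposition profile
#'
#' Integrates the TMDD system for repeated IV bolus dosing.  The full model
#' tracks free drug (central and peripheral amounts), free target and
#' drug-target complex with microscopic binding; the quasi-steady-state
#' (`"qss"`) reduction tracks total drug and total target and recovers free
#' drug from the binding quadratic, and is considerably faster.  Without
#' drug the free target rests at `ksyn/kdeg`.
#'
#' The full-model output includes cumulative linearly-eliminated and
#' internalised drug amounts, so total drug is conserved:
#' `dosed = central + peripheral + complex*V1 + eliminated + internalized`.
#'
#' @param p a [tmdd_params()]; the full model requires `kon`/`koff`.
#' @param reg a [regimen()] with route `"iv-bolus"`.
#' @param times non-decreasing time grid.
#' @param method `"full"` or `"qss"`.
#' @param rtol,atol solver tolerances; the system is stiff and is solved
#'   with `deSolve::lsoda`.
#' @return Data frame with columns `time`, `conc_free` (central free drug
#'   concentration), `target_free`, `complex`, `occupancy`
#'   (`complex/(target_free + complex)`), and for the full model the audit
#'   columns `amt_central`, `amt_peripheral`, `amt_eliminated`,
#'   `amt_internalized`.
#' @export
tmdd_profile <- function(p, reg, times, method = c("full", "qss"),
                         rtol = 1e-8, atol = 1e-10) {
  method <- match.arg(method)
  if (reg$route != "iv-bolus")
    .stopf("tmdd_profile supports IV bolus regimens only")
  if (is.unsorted(times) || any(times < 0))
    .stopf("'times' must be non-negative and non-decreasing")
  dose_times <- (seq_len(reg$n_doses) - 1L) * reg$tau
  grid <- sort(unique(c(times, dose_times)))
  solve_fail <- function(e)
    .stopf(paste0("TMDD solver failed (%s); consider looser tolerances ",
                  "[cl=%g v1=%g q=%g v2=%g ksyn=%g kdeg=%g kint=%g]"),
           conditionMessage(e), p$cl, p$v1, p$q, p$v2, p$ksyn, p$kdeg, p$kint)
  if (method == "full") {
    if (is.null(p$kon) || is.null(p$koff))
      .stopf("full TMDD model requires kon and koff")
    # states: A1 free drug central (amount), A2 peripheral (amount),
    # R free target (conc), P complex (conc), AEL, AINT (amounts)
    deriv <- function(t, y, parms) {
      C <- y[1] / p$v1
      bind <- p$kon * C * y[3]
      dA1 <- -p$cl * C - p$q * C + p$q * y[2] / p$v2 -
        bind * p$v1 + p$koff * y[4] * p$v1
      dA2 <- p$q * C - p$q * y[2] / p$v2
      dR <- p$ksyn - p$kdeg * y[3] - bind + p$koff * y[4]
      dP <- bind - (p$kint + p$koff) * y[4]
      list(c(dA1, dA2, dR, dP, p$cl * C, p$kint * y[4] * p$v1))
    }
    ev <- data.frame(var = "A1", time = dose_times, value = reg$dose,
                     method = "add")
    y0 <- c(A1 = 0, A2 = 0, R = p$r0, P = 0, AEL = 0, AINT = 0)
    sol <- tryCatch(
      deSolve::lsoda(y0, grid, deriv, parms = NULL, rtol = rtol, atol = atol,
                     events = list(data = ev)),
      error = solve_fail, warning = solve_fail)
    sol <- sol[match(times, sol[, 1L]), , drop = FALSE]
    R <- sol[, 4L]; P <- sol[, 5L]
    data.frame(time = times, conc_free = sol[, 2L] / p$v1,
               target_free = R, complex = P,
               occupancy = ifelse(R + P > 0, P / (R + P), 0),
               amt_central = sol[, 2L], amt_peripheral = sol[, 3L],
               amt_eliminated = sol[, 6L], amt_internalized = sol[, 7L])
  } else {
    # states: Ctot total drug central (conc), A2 peripheral (amount),
    # Rtot total target (conc)
    free_c <- function(ctot, rtot)
      0.5 * ((ctot - rtot - p$kss) +
               sqrt((ctot - rtot - p$kss)^2 + 4 * p$kss * ctot))
    deriv <- function(t, y, parms) {
      C <- free_c(y[1], y[3])
      occ <- C / (p$kss + C)
      dCtot <- -(p$cl / p$v1) * C - (p$q / p$v1) * C +
        p$q * (y[2] / p$v2) / p$v1 - p$kint * y[3] * occ
      dA2 <- p$q * C - p$q * y[2] / p$v2
      dRtot <- p$ksyn - p$kdeg * y[3] - (p$kint - p$kdeg) * y[3] * occ
      list(c(dCtot, dA2, dRtot))
    }
    ev <- data.frame(var = "CTOT", time = dose_times, value = reg$dose / p$v1,
                     method = "add")
    y0 <- c(CTOT = 0, A2 = 0, RTOT = p$r0)
    sol <- tryCatch(
      deSolve::lsoda(y0, grid, deriv, parms = NULL, rtol = rtol, atol = atol,
                     events = list(data = ev)),
      error = solve_fail, warning = solve_fail)
    sol <- sol[match(times, sol[, 1L]), , drop = FALSE]
    C <- free_c(sol[, 2L], sol[, 4L])
    P <- sol[, 4L] * C / (p$kss + C)
    R <- sol[, 4L] - P
    data.frame(time = times, conc_free = C, target_free = R, complex = P,
               occupancy = ifelse(R + P > 0, P / (R + P), 0))
  }
}
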