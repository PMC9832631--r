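# Independent oracles used across the suite.

# Closed-form two-compartment IV-bolus concentration (single dose at t = 0),
# the linear-PK reference for the no-target TMDD reduction.
twocomp_bolus_conc <- function(dose, cl, v1, q, v2, t) {
  k10 <- cl / v1; k12 <- q / v1; k21 <- q / v2
  s <- k10 + k12 + k21
  disc <- sqrt(s^2 - 4 * k10 * k21)
  al <- (s + disc) / 2
  be <- (s - disc) / 2
  dose / v1 * ((al - k21) / (al - be) * exp(-al * t) +
                 (k21 - be) / (al - be) * exp(-be * t))
}

# Brute-force nested Monte Carlo PoPS for a small, fully spelled-out study:
# one-compartment steady-state exposure driving a saturating fold-increase,
# 30% log-normal BSV on clearance, one benefit criterion with a uniform
# threshold prior.  Written as a naive double loop with base R samplers,
# following the engine's documented substream discipline but sharing none of
# its code path.
oracle_pops_brute <- function(seed, M, N, doses, tau, cl_typ, cv_cl,
                              em_meanlog, em_sdlog, ec50,
                              k_lower, k_upper, n_req) {
  sig <- sqrt(log(1 + (cv_cl / 100)^2))
  vapply(doses, function(dose) {
    passes <- vapply(seq_len(M), function(i) {
      draws <- withr::with_seed(pops_substream(seed, i, 0L), {
        # declared order: CL (point, no draw), Emax (log-normal),
        # EC50 (point, no draw); then criteria: K (uniform), n (point)
        emax_i <- exp(rnorm(1L, em_meanlog, em_sdlog))
        K_i <- runif(1L, k_lower, k_upper)
        c(emax_i, K_i)
      })
      etas <- withr::with_seed(pops_substream(seed, i, 1L),
        matrix(rnorm(N), N, 1L) %*% chol(matrix(sig^2, 1L, 1L)))
      cl_j <- cl_typ * exp(etas[, 1L])
      css <- (dose / (cl_j * tau)) * 1
      fold <- 1 + draws[1L] * css / (ec50 + css)
      mean(fold >= draws[2L]) >= n_req
    }, logical(1))
    mean(passes)
  }, numeric(1))
}

# Minimal endpoint model matching the oracle above, assembled by hand so the
# engine test does not route through the config layer.
oracle_fold_model <- function() {
  endpoint_model(
    name = "oracle_fold",
    params = c("CL", "Emax", "EC50"),
    endpoints = c("fold_increase", "css"),
    fn = function(P, reg, covariates = NULL) {
      css <- (reg$dose / (P[, "CL"] * reg$tau)) * 1
      fold <- 1 + P[, "Emax"] * css / (P[, "EC50"] + css)
      cbind(fold_increase = fold, css = css)
    })
}

# Simple exposure-only model for monotonicity checks.
css_only_model <- function() {
  endpoint_model(
    name = "css_only",
    params = "CL",
    endpoints = "css",
    fn = function(P, reg, covariates = NULL)
      cbind(css = reg$dose / (P[, "CL"] * reg$tau)))
}
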