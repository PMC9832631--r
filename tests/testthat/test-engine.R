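test_that("population simulation applies BSV on the declared scale", {
  model <- oracle_fold_model()
  theta <- c(CL = 5, Emax = 9, EC50 = 0.5)
  # no BSV: all subjects identical
  em <- simulate_population(model, regimen(100, 24), theta, bsv = NULL, N = 8)
  expect_equal(nrow(unique(em)), 1L)
  # reproducibility given a seed
  bsv <- bsv_spec(cv = c(CL = 30))
  e1 <- simulate_population(model, regimen(100, 24), theta, bsv, N = 50,
                            seed = 3)
  e2 <- simulate_population(model, regimen(100, 24), theta, bsv, N = 50,
                            seed = 3)
  expect_identical(e1, e2)
  # 30% CV on clearance is recovered in the simulated exposures
  big <- simulate_population(model, regimen(100, 24), theta, bsv, N = 1e5,
                             seed = 4)
  cl <- (100 / 24) / big[, "css"]
  expect_equal(sd(cl) / mean(cl), 0.30, tolerance = 0.03)
})

test_that("degenerate nesting collapses PoPS to a single indicator", {
  model <- oracle_fold_model()
  plan <- simulation_plan(doses = c(10, 100, 400), M = 20, N = 30, seed = 5,
                          tau = 24)
  unc <- list(fixed = list(CL = dist_point(5), Emax = dist_point(9),
                           EC50 = dist_point(0.5)))
  crit <- criteria_set(criterion("fold_increase", ">=", 4, 0.9, "benefit"))
  curve <- compute_pops(plan, model, crit, unc)
  expect_true(all(curve$pops %in% c(0, 1)))
  # the direct indicator on one deterministic population
  fold <- function(dose) 1 + 9 * (dose / (5 * 24)) / (0.5 + dose / (5 * 24))
  expect_equal(curve$pops, as.numeric(fold(plan$doses) >= 4))
})

test_that("unachievable criteria give PoPS zero at every dose", {
  model <- oracle_fold_model()
  plan <- simulation_plan(doses = c(10, 100), M = 10, N = 20, seed = 6)
  unc <- list(fixed = list(CL = dist_point(5), Emax = dist_point(9),
                           EC50 = dist_point(0.5)),
              bsv = bsv_spec(cv = c(CL = 30)))
  crit <- criteria_set(criterion("fold_increase", ">=", 50, 0.5, "benefit"))
  curve <- compute_pops(plan, model, crit, unc)
  expect_equal(curve$pops, c(0, 0))
})

test_that("engine matches the brute-force oracle on a tiny study", {
  model <- oracle_fold_model()
  plan <- simulation_plan(doses = c(20, 60, 180), M = 6, N = 4, seed = 11)
  unc <- list(fixed = list(CL = dist_point(5),
                           Emax = dist_lognormal(log(9), 0.2),
                           EC50 = dist_point(0.5)),
              bsv = bsv_spec(cv = c(CL = 30)))
  crit <- criteria_set(criterion("fold_increase", ">=",
                                 dist_uniform(2, 6), 0.75, "benefit"))
  curve <- compute_pops(plan, model, crit, unc)
  oracle <- oracle_pops_brute(seed = 11, M = 6, N = 4,
                              doses = c(20, 60, 180), tau = 24,
                              cl_typ = 5, cv_cl = 30,
                              em_meanlog = log(9), em_sdlog = 0.2,
                              ec50 = 0.5, k_lower = 2, k_upper = 6,
                              n_req = 0.75)
  expect_identical(curve$pops, oracle)
})

test_that("proportion bands follow type-7 percentiles", {
  fr <- seq(0, 0.99, by = 0.01)
  b <- proportion_bands(fr, level = 0.90)
  expect_equal(unname(b), unname(quantile(fr, c(0.5, 0.05, 0.95), type = 7)))
  expect_equal(unname(proportion_bands(rep(0.4, 10))),
               c(0.4, 0.4, 0.4))
  expect_true(all(b >= 0 & b <= 1))
})

test_that("optimal dose breaks ties towards the lowest dose", {
  mk <- function(pops) structure(data.frame(dose = c(10, 20, 40), pops = pops),
                                 class = c("pops_curve", "data.frame"))
  expect_equal(optimal_dose(mk(c(0.1, 0.5, 0.9)))$dose, 40)
  expect_equal(optimal_dose(mk(c(0.5, 0.5, 0.5)))$dose, 10)
  expect_equal(optimal_dose(mk(c(0.2, 0.9, 0.3)))$dose, 20)
})

test_that("common random numbers yield monotone curves for one-sided criteria", {
  model <- css_only_model()
  plan <- simulation_plan(doses = c(10, 30, 90, 270), M = 150, N = 150,
                          seed = 21)
  unc <- list(fixed = list(CL = dist_lognormal(log(5), 0.2)),
              bsv = bsv_spec(cv = c(CL = 30)))
  benefit <- criteria_set(criterion("css", ">=", dist_uniform(0.2, 0.6),
                                    0.8, "benefit"))
  risk <- criteria_set(criterion("css", ">", dist_uniform(0.2, 0.6),
                                 0.05, "risk"))
  cb <- compute_pops(plan, model, benefit, unc)
  cr <- compute_pops(plan, model, risk, unc)
  expect_true(all(diff(cb$pops) >= 0))
  expect_true(all(diff(cr$pops) <= 0))
  expect_true(any(cb$pops > 0) && any(cb$pops < 1))
})

test_that("doubling the population size shrinks the proportion noise by ~sqrt(2)", {
  model <- css_only_model()
  unc <- list(fixed = list(CL = dist_point(5)),
              bsv = bsv_spec(cv = c(CL = 30)))
  crit <- criteria_set(criterion("css", ">=", 0.25, 0.5, "benefit"))
  sd_at <- function(N) {
    plan <- simulation_plan(doses = 30, M = 400, N = N, seed = 22)
    curve <- compute_pops(plan, model, crit, unc)
    sd(attr(curve, "replicates")$fraction)
  }
  ratio <- sd_at(100) / sd_at(200)
  expect_gt(ratio, 1.2)
  expect_lt(ratio, 1.65)
})

test_that("the estimate stabilises as the number of trials grows", {
  model <- css_only_model()
  unc <- list(fixed = list(CL = dist_lognormal(log(5), 0.25)),
              bsv = bsv_spec(cv = c(CL = 30)))
  crit <- criteria_set(criterion("css", ">=", dist_uniform(0.2, 0.35),
                                 0.8, "benefit"))
  pops_at <- function(M) {
    plan <- simulation_plan(doses = 40, M = M, N = 100, seed = 23)
    compute_pops(plan, model, crit, unc)$pops
  }
  p1 <- pops_at(1000)
  p2 <- pops_at(4000)
  se <- sqrt(p1 * (1 - p1) / 1000)
  expect_lt(abs(p2 - p1), 2 * se)
})

test_that("scenario sweeps are factorial and degenerate to a plain run", {
  cfg <- make_case2_config(seed = 31, M = 20, N = 50)
  one <- scenario_analysis(cfg, axes = list(
    "uncertainty.bsv.cv.Emax" = c(mid = 40)))
  # a single cell at the base level: identical to the plain run with the
  # same overrides applied
  base <- cfg
  base$scenarios <- NULL
  base$criteria$safety$threshold <- list(family = "point",
                                         params = list(value = 3.5))
  expect_equal(one$curves[[1]]$pops, run_config(base)$pops)
  expect_equal(nrow(one$grid), 1L)
  expect_error(scenario_analysis(cfg, axes = list("model.typical.nope" = 1:2)),
               "unknown configuration path")
})

test_that("structural failures abort the replicate loudly", {
  model <- endpoint_model("fragile", "CL", "css",
    function(P, reg, covariates = NULL) {
      out <- cbind(css = reg$dose / (P[, "CL"] * reg$tau))
      out[1, 1] <- NA_real_
      out
    })
  plan <- simulation_plan(doses = 10, M = 2, N = 5, seed = 1)
  crit <- criteria_set(criterion("css", ">=", 0.1, 0.5, "benefit"))
  expect_error(
    compute_pops(plan, model, crit,
                 list(fixed = list(CL = dist_point(5)))),
    "missing endpoints for subject")
})
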