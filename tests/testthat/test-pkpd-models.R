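test_that("steady-state average concentration follows dose/(CL tau)", {
  expect_equal(css_average(regimen(0, 24), 10), 0)
  expect_equal(css_average(regimen(240, 24), 10), 1)
  expect_equal(css_average(regimen(480, 24), 10),
               2 * css_average(regimen(240, 24), 10))
  expect_error(css_average(regimen(10, 24), 0), "> 0")
})

test_that("Michaelis-Menten steady state solves the elimination balance", {
  # vmax = 0 reduces to the linear form
  expect_equal(css_average_mm(regimen(240, 24), 10, 0, 1),
               css_average(regimen(240, 24), 10))
  # balance audit: rate in == rate out at the returned concentration
  reg <- regimen(500, 28)
  css <- css_average_mm(reg, cl = 0.2, vmax = 1.5, km = 0.5)
  expect_equal(0.2 * css + 1.5 * css / (0.5 + css), 500 / 28,
               tolerance = 1e-12)
  expect_equal(css_average_mm(regimen(0, 28), 0.2, 1.5, 0.5), 0)
})

test_that("one-compartment profiles honour limits and superposition", {
  # IV bolus initial condition
  cb <- conc_profile_onecomp(list(cl = 10, v = 50),
                             regimen(100, 24, "iv-bolus"), times = c(0, 1))
  expect_equal(cb[1], 100 / 50)
  # washout long after the last dose
  cw <- conc_profile_onecomp(list(cl = 10, v = 50, ka = 1),
                             regimen(100, 24, "oral"), times = 2000)
  expect_lt(cw, 1e-12)
  # dose linearity
  p <- list(cl = 10, v = 50, ka = 1)
  t <- seq(0, 48, by = 0.5)
  expect_equal(conc_profile_onecomp(p, regimen(200, 24, "oral", 2), t),
               2 * conc_profile_onecomp(p, regimen(100, 24, "oral", 2), t))
  # ka == ke degenerate case: matches the nearby regular solution
  pe <- list(cl = 10, v = 50, ka = 10 / 50)
  pn <- list(cl = 10, v = 50, ka = 10 / 50 * (1 + 1e-7))
  expect_equal(conc_profile_onecomp(pe, regimen(100, 24, "oral"), t),
               conc_profile_onecomp(pn, regimen(100, 24, "oral"), t),
               tolerance = 1e-5)
})

test_that("steady-state interval AUC agrees with the closed form", {
  p <- list(cl = 10, v = 50, ka = 1.2)
  reg <- regimen(100, 24, "oral", n_doses = 30)
  t <- seq(29 * 24, 30 * 24, length.out = 241)
  conc <- conc_profile_onecomp(p, reg, t)
  auc <- auc_interval(t, conc, min(t), max(t))
  expect_equal(auc, css_average(reg, 10) * 24, tolerance = 1e-3)
})

test_that("site translation multiplies free fraction and partition", {
  part <- list(fu = 1, kp_uu = 1)
  expect_equal(site_free_concentration(3, part, "brain"), 3)
  expect_equal(site_free_concentration(10, list(fu = 0.1, kp_uu = 0.5),
                                       "brain"), 0.5)
  expect_equal(site_free_concentration(10, list(kp_tissue = 0.1), "tissue"), 1)
  expect_error(site_free_concentration(10, list(fu = 0.1), "brain"),
               "kp_uu")
  # a drawn kp_uu range maps exposure into the expected band
  kp <- dist_sample(dist_uniform(0.35, 0.50), 500, seed = 1)
  free <- site_free_concentration(10, list(fu = 0.1), "plasma")
  brain <- free * kp
  expect_true(all(brain >= 0.35 * free & brain <= 0.50 * free))
})

test_that("Emax model and its inverse are mutually consistent", {
  p <- list(emax = 1, ec50 = 2)
  expect_equal(emax_effect(0, p), 0)
  expect_equal(emax_effect(2, p), 0.5)
  expect_equal(emax_effect(18, p), 0.9)
  expect_equal(emax_inverse(0.5, p), 2)
  expect_equal(emax_inverse(0, p), 0)
  expect_equal(emax_inverse(0.9, p), 18)
  expect_error(emax_inverse(1, p), "Emax")
  # round trip to 1e-9 across effects and hill exponents
  for (hill in c(0.5, 1, 2.2)) {
    ph <- list(emax = 0.95, ec50 = 3, hill = hill)
    eff <- seq(0.01, 0.94, length.out = 25)
    expect_equal(emax_effect(emax_inverse(eff, ph), ph), eff,
                 tolerance = 1e-9)
  }
})

test_that("required central inhibition normalises a fold elevation", {
  expect_equal(required_central_inhibition(1), 0)
  expect_equal(required_central_inhibition(2), 0.5)
  expect_equal(required_central_inhibition(3), 2 / 3, tolerance = 1e-12)
  expect_error(required_central_inhibition(0.9), ">= 1")
  # a uniform fold prior maps into the expected inhibition band
  folds <- dist_sample(dist_uniform(1.5, 3.0), 200, seed = 2)
  req <- required_central_inhibition(folds)
  expect_true(all(req >= 1 / 3 & req <= 2 / 3))
})

test_that("turnover ODE preserves baseline and reaches analytic steady states", {
  eff <- list(emax = 0.8, ec50 = 1)
  p <- turnover_params(kin = 4, kout = 0.5, mode = "inhibit-production",
                       effect = eff)
  # no drug: flat at kin/kout
  flat <- turnover_profile(p, function(t) 0, times = seq(0, 50, 1))
  expect_equal(flat$response, rep(8, nrow(flat)), tolerance = 1e-7)
  # constant C = IC50, Imax 0.8: steady state 0.6 R0 (ten half-lives out)
  prof <- turnover_profile(p, function(t) 1, times = seq(0, 10 * log(2) / 0.5,
                                                         length.out = 80))
  expect_equal(prof$response[nrow(prof)], 0.6 * 8, tolerance = 0.005 * 4.8)
  expect_equal(turnover_steady_state(p, 1), 0.6 * 8)
  # stimulation with 3-fold Emax at saturating concentration: 4 R0
  ps <- turnover_params(kin = 4, kout = 0.5, mode = "stimulate-production",
                        effect = list(emax = 3, ec50 = 1))
  prof2 <- turnover_profile(ps, function(t) 1e6,
                            times = seq(0, 10 * log(2) / 0.5, length.out = 80))
  expect_equal(prof2$response[nrow(prof2)], 4 * 8, tolerance = 0.005 * 32)
  # loss modulation closed forms
  pl <- turnover_params(kin = 4, kout = 0.5, mode = "inhibit-loss",
                        effect = eff)
  expect_equal(turnover_steady_state(pl, 1), 8 / (1 - 0.4))
  # transit chain keeps the baseline and the final steady state
  pt <- turnover_params(kin = 4, kout = 0.5, mode = "inhibit-production",
                        effect = eff, n_transit = 3)
  proft <- turnover_profile(pt, function(t) 1,
                            times = seq(0, 25 * log(2) / 0.5, length.out = 120))
  expect_equal(proft$response[1], 8)
  expect_equal(proft$response[nrow(proft)], 0.6 * 8, tolerance = 0.005 * 4.8)
})

test_that("TMDD with no target collapses to linear two-compartment PK", {
  p <- tmdd_params(cl = 0.2, v1 = 3, q = 0.3, v2 = 2, kdeg = 0.1,
                   kint = 0.05, r0 = 0, kon = 1, koff = 0.01)
  reg <- regimen(100, tau = 28, route = "iv-bolus")
  t <- c(0.01, 0.5, 1, 3, 7, 14, 28)
  ref <- twocomp_bolus_conc(100, 0.2, 3, 0.3, 2, t)
  for (m in c("full", "qss")) {
    prof <- tmdd_profile(p, reg, times = t, method = m)
    expect_equal(prof$conc_free, ref, tolerance = 1e-3)
    expect_true(all(prof$target_free == 0))
  }
})

test_that("TMDD conserves drug mass and saturates target occupancy", {
  p <- tmdd_params(cl = 0.2, v1 = 3, q = 0.3, v2 = 2, kdeg = 0.1,
                   kint = 0.5, r0 = 5, kon = 2, koff = 0.1)
  tt <- setdiff(seq(0.25, 42, by = 0.25), c(14, 28))
  pr <- tmdd_profile(p, regimen(50, tau = 14, route = "iv-bolus", n_doses = 3),
                     times = tt)
  expect_true(all(pr$conc_free >= 0) && all(pr$target_free >= 0) &&
                all(pr$complex >= 0))
  total <- pr$amt_central + pr$amt_peripheral + pr$complex * 3 +
    pr$amt_eliminated + pr$amt_internalized
  dosed <- 50 * findInterval(pr$time, c(0, 14, 28))
  expect_lt(max(abs(total - dosed) / dosed), 1e-8)
  expect_true(all(pr$occupancy >= 0 & pr$occupancy <= 1))
  # free-drug exposure is superlinear in dose while the target saturates
  auc_free <- function(dose) {
    prof <- tmdd_profile(p, regimen(dose, tau = 60, route = "iv-bolus"),
                         times = seq(0, 60, 0.25))
    auc_interval(prof$time, prof$conc_free)
  }
  expect_gt(auc_free(10) / auc_free(5), 2)
})

test_that("allometric scaling applies the conventional exponents", {
  expect_equal(allometric_scale(5, "clearance", 70, 70), 5)
  expect_equal(allometric_scale(1, "clearance", 3, 70), 10.6,
               tolerance = 0.005)
  expect_equal(allometric_scale(2, "volume", 10, 30), 6)
})

test_that("trapezoidal AUC matches rectangles and exponential closed form", {
  t <- seq(0, 24, length.out = 100)
  expect_equal(auc_interval(t, rep(3, 100), 0, 24), 72)
  expect_equal(auc_interval(t, rep(0, 100)), 0)
  ke <- 0.1
  conc <- 5 * exp(-ke * t)
  expect_equal(auc_interval(t, conc, 0, 24), 5 / ke * (1 - exp(-ke * 24)),
               tolerance = 1e-3)
  expect_error(auc_interval(t, conc, 10, 10), "t0")
  expect_error(auc_interval(t, conc, 0, 30), "span")
})
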