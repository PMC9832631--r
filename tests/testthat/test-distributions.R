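test_that("point masses and degenerate specs draw exactly, without RNG use", {
  specs <- list(CL = dist_point(10), EC50 = dist_point(0.5))
  x <- draw_fixed_effects(specs, M = 4, seed = 1)
  expect_true(all(x[, "CL"] == 10) && all(x[, "EC50"] == 0.5))

  expect_equal(dist_sample(weighted_categorical(7, 1), 10, seed = 1),
               rep(7, 10))
  expect_equal(unique(dist_sample(weighted_categorical(1:3, c(0, 0, 1)),
                                  1000, seed = 2)), 3)

  # point draws must not consume random numbers: a stream that draws a point
  # then a uniform equals one that draws the uniform alone
  a <- withr::with_seed(9, {
    dist_sample(dist_point(5), 1); dist_sample(dist_uniform(0, 1), 1)
  })
  b <- withr::with_seed(9, dist_sample(dist_uniform(0, 1), 1))
  expect_identical(a, b)
})

test_that("invalid specifications are rejected with informative errors", {
  expect_error(dist_uniform(2, 1), "lower < upper")
  expect_error(scaled_beta(0.5, 1, 16), "outside support")
  expect_error(scaled_beta(2, 1, 16, concentration = 2), "concentration")
  expect_error(weighted_categorical(1:2, c(1, -1)), "non-negative")
  expect_error(weighted_categorical(1:2, c(0, 0)), "positive")
  expect_error(dist_spec("weibull", list(shape = 1)), "unknown distribution family")
  expect_error(cv_to_lognormal_sigma(-5), "non-negative")
  # correlation restricted to normal / log-normal marginals
  cm <- matrix(c(1, .5, .5, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(
    draw_fixed_effects(list(a = dist_uniform(0, 1), b = dist_normal(0, 1)),
                       correlation = cm, M = 2, seed = 1),
    "normal or log-normal")
})

test_that("percent CV converts to the closed-form log-scale SD", {
  expect_equal(cv_to_lognormal_sigma(0), 0)
  expect_equal(cv_to_lognormal_sigma(30), sqrt(log(1.09)))
  expect_equal(round(cv_to_lognormal_sigma(30), 4), 0.2936)
  expect_equal(cv_to_lognormal_sigma(100), sqrt(log(2)))
  expect_equal(round(cv_to_lognormal_sigma(100), 4), 0.8326)
})

test_that("empirical marginals match analytic moments and supports", {
  # uniform translation prior: support respected, mean within 3 SE
  x <- dist_sample(dist_uniform(0.45, 0.75), 1e4, seed = 11)
  expect_gte(min(x), 0.45)
  expect_lte(max(x), 0.75)
  se <- (0.75 - 0.45) / sqrt(12 * 1e4)
  expect_lt(abs(mean(x) - 0.60), 3 * se)

  # log-normal BSV preserves the median at the typical value
  eta <- draw_subject_etas(matrix(cv_to_lognormal_sigma(30)^2, 1, 1),
                           N = 1e5, seed = 12)
  cl <- 10 * exp(eta[, 1])
  expect_equal(median(cl), 10, tolerance = 0.01)

  # 1-D eta variance within 3% of requested
  expect_equal(var(eta[, 1]), cv_to_lognormal_sigma(30)^2, tolerance = 0.03)
})

test_that("weighted categorical frequencies recover the 60:30:10 weights", {
  x <- dist_sample(weighted_categorical(c(1.2, 2.0, 3.5), c(60, 30, 10)),
                   1e5, seed = 13)
  p <- as.numeric(table(factor(x, levels = c(1.2, 2.0, 3.5)))) / 1e5
  target <- c(0.6, 0.3, 0.1)
  for (k in 1:3) {
    se <- sqrt(target[k] * (1 - target[k]) / 1e5)
    expect_lt(abs(p[k] - target[k]), 3 * se)
  }
})

test_that("scaled beta places its mode and respects its support", {
  d <- scaled_beta(mode = 2, lower = 1, upper = 16, concentration = 4)
  x <- dist_sample(d, 1e5, seed = 14)
  expect_gte(min(x), 1)
  expect_lte(max(x), 16)
  # empirical unit-bin histogram peak matches the analytic peak bin, which
  # contains the requested mode 2 (analytic masses via pbeta are the oracle)
  sh <- c(2 / 15 * 2 + 1, (1 - 1 / 15) * 2 + 1)
  analytic <- diff(pbeta((0:15) / 15, sh[1], sh[2]))
  emp <- as.numeric(table(cut(x, breaks = 1:16, include.lowest = TRUE)))
  expect_equal(which.max(emp), which.max(analytic))
  peak <- which.max(emp)
  expect_true(peak <= 2 && peak + 1 >= 2)  # peak bin [2, 3) contains 2

  # mode at the lower bound: monotonically decreasing density
  xb <- dist_sample(scaled_beta(mode = 1, lower = 1, upper = 16,
                                concentration = 4), 1e5, seed = 15)
  mb <- as.numeric(table(cut(xb, breaks = seq(1, 16, by = 3),
                             include.lowest = TRUE)))
  expect_true(all(diff(mb) < 0))
})

test_that("correlated log-normal draws recover the requested dependence", {
  cm <- matrix(c(1, 0.9, 0.9, 1), 2,
               dimnames = list(c("Emax", "EC50"), c("Emax", "EC50")))
  x <- draw_fixed_effects(
    list(Emax = dist_lognormal(log(9), 0.3),
         EC50 = dist_lognormal(log(0.5), 0.25)),
    correlation = cm, M = 2e4, seed = 16)
  expect_equal(cor(log(x[, "Emax"]), log(x[, "EC50"])), 0.9,
               tolerance = 0.025)
  # marginal medians unaffected by the coupling
  expect_equal(median(x[, "Emax"]), 9, tolerance = 0.02)
})

test_that("samplers are reproducible and independent across substreams", {
  specs <- list(k = dist_uniform(0, 1), m = dist_lognormal(0, 0.3))
  expect_identical(draw_fixed_effects(specs, M = 5, seed = 3),
                   draw_fixed_effects(specs, M = 5, seed = 3))
  # replicate i's draw does not depend on how many replicates are requested
  expect_identical(draw_fixed_effects(specs, M = 3, seed = 3),
                   draw_fixed_effects(specs, M = 5, seed = 3)[1:3, ])

  om <- matrix(c(0.09, 0.03, 0.03, 0.04), 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  expect_identical(draw_subject_etas(om, 100, seed = 4),
                   draw_subject_etas(om, 100, seed = 4))
  expect_false(isTRUE(all.equal(draw_subject_etas(om, 100, seed = 4),
                                draw_subject_etas(om, 100, seed = 5))))
})

test_that("degenerate and invalid covariance matrices are handled", {
  z <- draw_subject_etas(matrix(0, 2, 2,
                                dimnames = list(c("a", "b"), c("a", "b"))),
                         N = 7, seed = 1)
  expect_true(all(z == 0))
  bad <- matrix(c(1, 2, 2, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(draw_subject_etas(bad, 5, seed = 1),
               "positive semidefinite")
  # semidefinite (one zero-variance component) still works
  semi <- diag(c(0.09, 0))
  dimnames(semi) <- list(c("a", "b"), c("a", "b"))
  z2 <- draw_subject_etas(semi, 1000, seed = 2)
  expect_true(all(z2[, 2] == 0))
  expect_gt(sd(z2[, 1]), 0.2)
})
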