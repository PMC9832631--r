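test_that("case 1 fixture encodes the anchored study conditions", {
  cfg <- make_case1_config(seed = 71)
  kpA <- cfg$compounds$A$uncertainty$fixed$kp_uu$params
  kpB <- cfg$compounds$B$uncertainty$fixed$kp_uu$params
  expect_identical(c(kpA$lower, kpA$upper), c(0.45, 0.75))
  expect_identical(c(kpB$lower, kpB$upper), c(0.35, 0.50))
  for (cc in cfg$compounds) {
    fe <- cc$uncertainty$fixed$fold_elevation$params
    expect_identical(c(fe$lower, fe$upper), c(1.5, 3.0))
    expect_equal(cc$uncertainty$bsv$cv, list(CL = 30, EC50 = 30))
    expect_equal(cc$criteria$balance$required_proportion, 0.80)
    expect_equal(cc$criteria$over_inhibition$required_proportion, 0.05)
    expect_equal(cc$criteria$over_inhibition$kind, "risk")
  }
  # every synthetic value is documented
  expect_true(all(nzchar(cfg$meta$notes)))
})

test_that("fixture configurations survive the YAML round trip", {
  cfg <- make_case1_config(seed = 72)$compounds$A
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, f)
  reloaded <- load_config(f)
  expect_true(isTRUE(all.equal(reloaded, cfg, tolerance = 1e-12)))
})

test_that("case 2 fixture matches its declared priors and scenario grid", {
  cfg <- make_case2_config(seed = 73)
  th <- cfg$criteria$pharmacology$threshold
  expect_equal(th$family, "scaled_beta")
  expect_equal(th$params$mode, 2)
  expect_equal(th$params$upper, 16)
  saf <- cfg$criteria$safety$threshold
  expect_equal(saf$params$weights, c(60, 30, 10))
  expect_equal(length(cfg$scenarios$axes[[1]]) *
                 length(cfg$scenarios$axes[[2]]), 9L)
  # the scenario grid itself has 3 x 3 cells
  scen <- scenario_analysis(make_case2_config(seed = 73, M = 5, N = 20))
  expect_equal(nrow(scen$grid), 9L)
  expect_equal(length(scen$curves), 9L)
})

test_that("restricting the safety prior to its most favourable species never lowers PoPS", {
  cfg <- make_case2_config(seed = 74, M = 60, N = 120)
  cfg$scenarios <- NULL
  base <- run_config(cfg)
  mono <- set_config_path(cfg, "criteria.safety.threshold",
                          list(family = "point", params = list(value = 3.5)))
  restricted <- run_config(mono)
  expect_true(all(restricted$pops >= base$pops))
})

test_that("case 3 fixture records the anchored prior and plan sizes", {
  cfg <- make_case3_config(seed = 75)
  pr <- cfg$criteria$pharmacology$threshold$params
  expect_identical(c(pr$lower, pr$upper), c(0.70, 0.95))
  expect_equal(cfg$plan$M, 500)
  expect_equal(cfg$plan$N, 500)
  expect_equal(cfg$plan$tau, 28)
})

test_that("case 4 fixture pairs N = 3000 and is symmetric in overlap", {
  cfg <- make_case4_config(seed = 76)
  expect_equal(cfg$pta$n, 3000)
  res <- run_pta_config(cfg)
  expect_equal(length(res$candidate$values), 3000L)
  swapped <- attainment_vs_benchmark(res$benchmark, res$candidate)
  direct <- attainment_vs_benchmark(res$candidate, res$benchmark)
  expect_equal(swapped$overlap, direct$overlap, tolerance = 1e-12)
})

test_that("fixtures are deterministic: same seed, byte-identical outputs", {
  cfg <- make_case1_config(seed = 77, M = 20, N = 50)
  r1 <- run_config(cfg$compounds$A)
  r2 <- run_config(cfg$compounds$A)
  expect_identical(r1$pops, r2$pops)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_results(r1, d1)
  write_results(r2, d2)
  for (f in c("pops_curve.csv", "replicates.csv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  # pta outputs are equally deterministic
  p1 <- withr::local_tempdir(); p2 <- withr::local_tempdir()
  write_results(run_pta_config(make_case4_config(seed = 78, n = 200)), p1)
  write_results(run_pta_config(make_case4_config(seed = 78, n = 200)), p2)
  expect_identical(readLines(file.path(p1, "index_distributions.csv")),
                   readLines(file.path(p2, "index_distributions.csv")))
})

test_that("write_case_fixture emits configs, inputs and golden outputs", {
  d <- withr::local_tempdir()
  write_case_fixture(4, seed = 79, out_dir = d, n = 300)
  expect_true(file.exists(file.path(d, "case4.yaml")))
  expect_true(file.exists(file.path(d, "case4_benchmark_mic_synthetic.csv")))
  expect_true(file.exists(file.path(d, "pta_summary.json")))
  tab <- read.csv(file.path(d, "case4_benchmark_mic_synthetic.csv"))
  expect_true(all(diff(tab$cumulative_fraction) >= 0))
})
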