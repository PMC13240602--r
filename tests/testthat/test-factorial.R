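test_that("the run matrix counts ALL plus one run per factor", {
  m <- build_run_matrix()
  expect_equal(nrow(m), 4)
  expect_equal(m$run[1], "ALL")
  expect_setequal(m$run, c("ALL", "no_climate", "no_co2", "no_disturbance"))
  m5 <- build_run_matrix(pre_boundary = 1918)
  expect_equal(nrow(m5), 5)
  expect_true("no_disturbance_before_1918" %in% m5$run)
  expect_identical(build_run_matrix(), build_run_matrix())
  expect_error(build_run_matrix(c("climate", "nitrogen")), "unknown factor")
})

test_that("a factor that does not vary contributes exactly zero", {
  p <- pft_params()
  # forcing with constant CO2: fixing CO2 changes nothing
  df <- as.data.frame(flat_forcing(1750:1860))
  df$co2_ppm <- 289
  f <- carbon_forcing(df)
  runs <- run_factorial(build_run_matrix(c("co2", "disturbance")), p, f)
  att <- attribute_nbp(runs, c(1800, 1860))
  expect_identical(att$contributions[["co2"]], 0)
  # no disturbance anywhere: all three disturbance channels and the
  # residual are zero
  expect_identical(att$contributions[["dist_immediate"]], 0)
  expect_identical(att$contributions[["dist_decomposition"]], 0)
  expect_identical(att$contributions[["dist_recovery"]], 0)
  expect_equal(att$net_disturbance, 0)
  expect_equal(att$closure_residual, 0)
})

test_that("disturbance channels sum to the run-differenced NBP", {
  p <- pft_params()
  set.seed(17)
  df <- as.data.frame(gen_forcing(1750:1960, 2, seed = 14))
  df$burned_frac <- pmin(rlnorm(nrow(df), log(0.006), 0.8), 0.5)
  df$harvest_frac <- pmin(pmax(rnorm(nrow(df), 0.002, 0.001), 0), 0.1)
  f <- carbon_forcing(df)
  runs <- run_factorial(build_run_matrix(), p, f)
  att <- attribute_nbp(runs, c(1900, 1960))
  led_all <- flux_ledger(runs$ALL, "total")
  led_nd <- flux_ledger(runs$no_disturbance, "total")
  sel <- led_all$year >= 1900 & led_all$year <= 1960
  total <- mean(led_all$nbp[sel] - led_nd$nbp[sel])
  expect_equal(att$net_disturbance, total, tolerance = 1e-9)
  scale <- max(abs(att$net_disturbance), 1e-6)
  expect_lt(abs(att$closure_residual) / scale, 0.01)
})

test_that("the attribution bookkeeping identity holds for supplied channels", {
  a <- attribution_result(dist_immediate = -30, dist_decomposition = -19,
                          dist_recovery = 85, window = c(1940, 1960))
  expect_equal(a$net_disturbance, 36)
  b <- attribution_result(dist_recovery = 80, dist_immediate = -128,
                          nbp_all_minus_nodist = -48)
  expect_equal(b$net_disturbance, -48)
  expect_equal(b$closure_residual, 0)
})

test_that("co2 sensitivity equals the channel over the mean excess", {
  p <- pft_params(gamma = 0.5)
  f <- flat_forcing(1750:1960)
  runs <- run_factorial(build_run_matrix("co2"), p, f)
  w <- c(1930, 1960)
  att <- attribute_nbp(runs, w)
  sel <- runs$ALL$years >= w[1] & runs$ALL$years <= w[2]
  excess <- mean(runs$ALL$co2_used[sel] - runs$ALL$params$c0)
  expect_equal(co2_sensitivity(runs, w),
               att$contributions[["co2"]] / excess, tolerance = 1e-12)
  expect_gt(co2_sensitivity(runs, w), 0)
  # degenerate: CO2 never leaves the reference -> undefined
  df <- as.data.frame(f)
  df$co2_ppm <- 289
  runs0 <- run_factorial(build_run_matrix("co2"), p, carbon_forcing(df))
  expect_error(co2_sensitivity(runs0, w), "undefined")
})

test_that("ensemble attribution brackets the per-scenario values", {
  p <- pft_params()
  spec <- scenario_spec(years = 1750:1960, n_cells = 2, seed = 23)
  sc <- gen_scenarios(spec)
  mat <- build_run_matrix("disturbance")
  rs <- list()
  init <- NULL
  for (nm in names(sc)[c(1, 3)]) {  # one mean, one inferred member
    rs[[nm]] <- run_factorial(mat, p, sc[[nm]], init = init)
    init <- rs[[nm]]$ALL$spinup
  }
  em <- attribute_ensemble(rs, c(1930, 1950))
  per <- em$per_scenario["net_disturbance", ]
  expect_equal(unname(em$lower[["net_disturbance"]]), min(per))
  expect_equal(unname(em$upper[["net_disturbance"]]), max(per))
  expect_gte(em$mean$net_disturbance, em$lower[["net_disturbance"]])
  expect_lte(em$mean$net_disturbance, em$upper[["net_disturbance"]])
})
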