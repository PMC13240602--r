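test_that("co2_response matches its closed form and limits", {
  expect_equal(co2_response(289, 289, 0.7), 1.0)
  expect_equal(co2_response(2 * 400, 400, 0), 1.0)
  # direct evaluation over the historical concentration range
  expect_equal(co2_response(420, 289, 0.5), 1 + 0.5 * log(420 / 289),
               tolerance = 1e-12)
  expect_equal(co2_response(420, 289, 0.5), 1.1869, tolerance = 1e-4)
  # clipped at zero for extreme depletion
  expect_equal(co2_response(1e-6, 400, 1), 0)
  expect_error(co2_response(-1, 289, 0.5), "positive")
  expect_error(co2_response(420, 0, 0.5), "positive")
})

test_that("step_year: empty system stays empty with zero fluxes", {
  p <- pft_params(gpp_max = 1e-300)  # effectively zero production
  st <- step_year(carbon_pools(), 0, p, 0, p$c0)
  expect_equal(total_carbon(st$pools), 0)
  expect_equal(unname(st$fluxes[c("gpp", "ra", "rh", "nbp")]),
               rep(0, 4))
  expect_equal(st$age, 1)
})

test_that("step_year satisfies the ledger identities and carbon closure", {
  p <- pft_params()
  set.seed(7)
  for (i in 1:25) {
    pools <- carbon_pools(green_leaf = runif(1), brown_leaf = runif(1),
                          stem = 5 * runif(1), root = 2 * runif(1),
                          litter = 4 * runif(1), soil = 10 * runif(1),
                          products_short = runif(1), products_long = runif(1))
    st <- step_year(pools, sample(0:150, 1), p,
                    rnorm(1, 0, 1), runif(1, 280, 450))
    fl <- st$fluxes
    expect_equal(fl[["er"]], fl[["ra"]] + fl[["rh"]], tolerance = 1e-12)
    expect_equal(fl[["nep"]], fl[["gpp"]] - fl[["er"]], tolerance = 1e-12)
    expect_equal(fl[["nbp"]],
                 fl[["nep"]] - fl[["fire_co2"]] - fl[["product_emission"]],
                 tolerance = 1e-12)
    # independent ledger summation: pool change must equal NBP
    dC <- total_carbon(st$pools) - total_carbon(pools)
    expect_equal(dC, fl[["nbp"]], tolerance = 1e-9)
  }
})

test_that("step_year rejects non-finite forcing", {
  p <- pft_params()
  expect_error(step_year(carbon_pools(stem = 1), 10, p, NaN, 400),
               "non-finite")
  expect_error(step_year(carbon_pools(stem = 1), 10, p, 0.3, NA),
               "non-finite")
})

test_that("spin-up reaches a fixed point of the annual step", {
  p <- fast_params()
  sp <- run_spinup(p, rep(0, 25))
  expect_lt(sp$cycles, 30)
  # replaying one year at equilibrium barely moves the state
  st <- step_year(sp$pools, sp$age, p, 0, p$c0)
  expect_lt(abs(st$fluxes[["nep"]]), 1e-4)
  # replaying a whole forcing cycle changes total carbon by < tol
  pools <- sp$pools
  age <- sp$age
  for (k in 1:25) {
    st <- step_year(pools, age, p, 0, p$c0)
    pools <- st$pools
    age <- st$age
  }
  expect_lt(abs(total_carbon(pools) - total_carbon(sp$pools)), 1e-4)
})

test_that("spin-up degenerate tolerance, determinism and failure mode", {
  p <- fast_params()
  expect_equal(run_spinup(p, rep(0, 25), tol = Inf)$cycles, 1)
  a <- run_spinup(p, rnorm(25), tol = 1e-3)
  b <- run_spinup(p, rnorm(25), tol = 1e-3)  # rnorm differs, seed state moves
  s1 <- run_spinup(p, rep(0.2, 25))
  s2 <- run_spinup(p, rep(0.2, 25))
  expect_identical(s1, s2)
  expect_error(run_spinup(pft_params(), rep(0, 25), tol = 1e-12,
                          max_cycles = 2),
               "slowest pool")
  expect_error(run_spinup(p, rep(0, 10)), "at least 25")
})

test_that("zero-disturbance transient equals the single-tile counterfactual", {
  p <- pft_params()
  f <- flat_forcing(1750:1850)
  tiled <- carbon_sim(p, f, drivers = driver_spec(disturbance = "on"),
                      tiling = TRUE)
  single <- run_transient(tiled$spinup, p, f,
                          drivers = driver_spec(disturbance = "off"),
                          tiling = FALSE)
  expect_equal(tiled$fluxes$nbp, single$fluxes$nbp, tolerance = 1e-14)
  expect_equal(tiled$fluxes$gpp, single$fluxes$gpp, tolerance = 1e-14)
  expect_true(all(tiled$fluxes$fire_co2 == 0))
  expect_true(all(tiled$tile_count == 1))
})

test_that("whole-run carbon closure holds on a disturbed multi-tile run", {
  p <- pft_params()
  set.seed(31)
  f <- as.data.frame(gen_forcing(1750:2000, 1, seed = 9))
  f$burned_frac <- pmin(rlnorm(nrow(f), log(0.004), 1), 0.8)
  f$harvest_frac <- pmin(pmax(rnorm(nrow(f), 0.002, 0.001), 0), 0.1)
  sim <- carbon_sim(p, carbon_forcing(f))
  expect_lt(sim$max_closure_residual, 1e-9)
  c0 <- total_carbon(sim$spinup[[1]]$pools)
  c_end <- sim$total_c[length(sim$years), 1]
  drift <- abs((c_end - c0) - sum(sim$fluxes$nbp[, 1])) / c_end
  expect_lt(drift, 1e-6)
  expect_true(all(sim$tile_count <= 12))
})

test_that("GPP recovery is monotone in age up to its plateau", {
  p <- pft_params()
  ages <- 0:120
  gpp <- sapply(ages, function(a)
    step_year(carbon_pools(), a, p, 0, p$c0)$fluxes[["gpp"]])
  expect_true(all(diff(gpp) >= -1e-14))
  expect_gt(gpp[60], 0.9 * gpp[121])
})

test_that("window-mean NBP is non-decreasing in gamma under rising CO2", {
  f <- flat_forcing(1750:1980)
  sims <- lapply(c(0, 0.25, 0.5, 1), function(g) {
    p <- pft_params(gamma = g)
    carbon_sim(p, f, drivers = driver_spec(disturbance = "off"),
               tiling = FALSE)
  })
  mean_nbp <- sapply(sims, function(s) {
    sel <- s$years >= 1940 & s$years <= 1980
    mean(s$fluxes$nbp[sel, ])
  })
  expect_true(all(diff(mean_nbp) > 0))
})

test_that("protocol and forcing validation errors are informative", {
  expect_error(sim_protocol("site", spinup_year = 1950, loop_until = 1900),
               "out of order")
  p <- pft_params()
  f <- flat_forcing(1750:1760)
  expect_error(carbon_sim(p, f), "at least one climate loop")
  df <- as.data.frame(flat_forcing(1750:1800))
  df <- df[df$year != 1775, ]
  expect_error(carbon_sim(p, carbon_forcing(df)), "consecutive")
})
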