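test_that("national totals follow unit arithmetic and linearity", {
  # 0.1 kg C m-2 yr-1 over 1e12 m2 is 100 Tg C yr-1
  expect_equal(national_summary(0.1, 1e12), 100)
  expect_equal(national_summary(c(0.1, 0.2), c(1e12, 1e12)), 300)
  # linear and order-invariant
  x <- c(0.03, 0.11, 0.07); a <- c(2e11, 3e11, 4e11)
  expect_equal(national_summary(2 * x, a), 2 * national_summary(x, a))
  perm <- c(3, 1, 2)
  expect_equal(national_summary(x[perm], a[perm]), national_summary(x, a))
  expect_equal(national_summary(rep(0, 3), a), 0)
  expect_error(national_summary(x, c(1, -1, 1)), "positive")
})

test_that("carbon to CO2 conversion uses the 44/12 molar ratio", {
  expect_equal(c_to_co2(210), 770)
  expect_equal(c_to_co2(12), 44)
  expect_equal(c_to_co2(259), 949 + 2 / 3, tolerance = 1e-12)
})

test_that("the balance sheet aggregates a run's pools and fluxes", {
  p <- pft_params()
  f <- flat_forcing(1750:1800)
  sim <- carbon_sim(p, f, drivers = driver_spec(disturbance = "off"))
  ns <- national_summary(sim, window = c(1790, 1800))
  # pool totals: per-m2 pools times domain area
  sel <- sim$years >= 1790
  expect_equal(sum(ns$pools_pg),
               mean(sim$total_c[sel, ]) * sim$cell_area *
                 length(sim$cells) * 1e-12,
               tolerance = 1e-9)
  expect_equal(ns$fluxes_tg_co2[["nbp"]], ns$fluxes_tg[["nbp"]] * 44 / 12)
  expect_output(print(ns), "balance sheet")
})

test_that("rolling trends recover exact slopes and degenerate cases", {
  r <- rolling_trend(2 * (1:40), years = 1:40, window = 15)
  expect_equal(nrow(r), 26)
  expect_lt(max(abs(r$slope - 2)), 1e-10)
  expect_lt(max(r$p_value), 1e-12)
  expect_false(any(r$significant_negative))
  # constant series: zero slope, non-significant
  rc <- rolling_trend(rep(1.3, 20), years = 1:20)
  expect_equal(rc$slope, rep(0, 6))
  expect_equal(rc$p_value, rep(1, 6))
  expect_error(rolling_trend(1:10, window = 15), "shorter")
})

test_that("a collapsing series is flagged where the running mean flips sign", {
  yrs <- 1980:2023
  s <- 10 - 0.8 * (yrs - 1980)  # crosses zero in 1992
  r <- rolling_trend(s, yrs)
  expect_true(all(r$significant_negative))
  expect_true(any(r$flag_sign_change))
  # strongly positive series is never flagged
  r2 <- rolling_trend(s + 100, yrs)
  expect_false(any(r2$flag_sign_change))
})

test_that("type-I error of the window test sits at the nominal level", {
  set.seed(2024)
  n_rep <- 1000
  rejections <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    r <- rolling_trend(rnorm(15), years = 1:15, window = 15)
    rejections[i] <- r$p_value[1] < 0.05
  }
  rate <- mean(rejections)
  # binomial 99.7% band around 0.05 for n = 1000
  band <- 3 * sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(rate - 0.05), band + 1e-12)
})

test_that("crossing year is exact on linear members and reports non-crossers", {
  yrs <- 1990:2023
  cx <- crossing_year(10 - (yrs - 2011), yrs)
  expect_equal(cx$crossing, 2021, tolerance = 1e-8)
  ens <- sapply(c(2019, 2020, 2022, 2023), function(y0) y0 - yrs)
  cx4 <- crossing_year(ens, yrs)
  expect_equal(cx4$mean, 2021, tolerance = 1e-8)
  expect_equal(cx4$sd, sd(c(2019, 2020, 2022, 2023)), tolerance = 1e-8)
  expect_equal(cx4$n_crossing, 4)
  # flat positive series: distinguished non-crossing result, no error
  cx0 <- crossing_year(rep(5, length(yrs)), yrs)
  expect_equal(cx0$n_no_crossing, 1)
  expect_true(is.na(cx0$mean))
  expect_output(print(cx0), "no ensemble member crosses")
  expect_error(crossing_year(1:10, 1:10), "too short")
})

test_that("crossing recovery tolerates noise at 20% of the trend", {
  yrs <- 1980:2023
  set.seed(77)
  ens <- sapply(1:40, function(i)
    (2021 - yrs) + rnorm(length(yrs), 0, 0.2 * 15))
  cx <- crossing_year(ens, yrs)
  expect_lt(abs(cx$mean - 2021), 1)
})
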