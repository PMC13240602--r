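test_that("splitting moves the disturbed fraction to a new age-0 tile", {
  t0 <- tile_set(1, 80, carbon_pools(stem = 5, litter = 2, soil = 10))
  r <- split_tiles(t0, burned_frac = 0.1)
  expect_equal(sort(r$tiles$area), c(0.1, 0.9))
  expect_equal(r$tiles$age[r$tiles$area == 0.1], 0)
  expect_equal(sum(r$tiles$area), 1, tolerance = 1e-15)
  # no disturbance: unchanged, zero fluxes
  r0 <- split_tiles(t0, 0, 0)
  expect_identical(r0$tiles, t0)
  expect_equal(r0$fire_co2, 0)
  # demanded disturbance exceeding the cell errors
  expect_error(split_tiles(t0, 0.7, 0.5), "exceeds available area")
})

test_that("split conserves carbon: pools + fire CO2 balance exactly", {
  set.seed(5)
  for (i in 1:10) {
    tiles <- random_tiles(5)
    b <- runif(1, 0, 0.4)
    h <- runif(1, 0, 0.3)
    before <- standcycle:::tile_total_carbon(tiles)
    r <- split_tiles(tiles, b, h)
    after <- standcycle:::tile_total_carbon(r$tiles)
    expect_equal(after + r$fire_co2, before, tolerance = 1e-12)
    expect_equal(sum(r$tiles$area), 1, tolerance = 1e-12)
  }
})

test_that("oldest-first draw takes area from the oldest tiles", {
  tiles <- tile_set(c(0.5, 0.5), c(10, 100),
                    cbind(unclass(carbon_pools(stem = 1)),
                          unclass(carbon_pools(stem = 9))))
  r <- split_tiles(tiles, 0.25, 0, draw = "oldest")
  # disturbed composition equals the old tile's state
  new_tile <- which(r$tiles$age == 0)
  expect_equal(unname(r$tiles$pools["stem", new_tile]),
               partition_fire(carbon_pools(stem = 9))$pools[["stem"]])
})

test_that("merging respects the cap and conserves area and carbon", {
  set.seed(8)
  tiles <- random_tiles(13)
  before_c <- standcycle:::tile_total_carbon(tiles)
  m <- merge_tiles(tiles, 12)
  expect_equal(standcycle:::n_tiles(m), 12)
  expect_equal(sum(m$area), 1, tolerance = 1e-12)
  expect_equal(standcycle:::tile_total_carbon(m), before_c,
               tolerance = 1e-12)
  # already under the cap: unchanged
  expect_identical(merge_tiles(m, 12), m)
  # equal-age tiles collapse to one with area-weighted pools
  two <- tile_set(c(0.25, 0.75), c(30, 30),
                  cbind(unclass(carbon_pools(stem = 4)),
                        unclass(carbon_pools(stem = 8))))
  one <- merge_tiles(two, 1)
  expect_equal(standcycle:::n_tiles(one), 1)
  expect_equal(unname(one$pools["stem", 1]), 0.25 * 4 + 0.75 * 8)
})

test_that("split+merge conserve area and carbon over long random histories", {
  set.seed(99)
  tiles <- tile_set(1, 50, carbon_pools(stem = 5, litter = 2, soil = 10))
  for (yr in 1:1000) {
    b <- min(rlnorm(1, log(0.01), 1), 0.5)
    h <- runif(1, 0, 0.05)
    before <- standcycle:::tile_total_carbon(tiles)
    r <- split_tiles(tiles, b, h)
    tiles <- merge_tiles(r$tiles, 12)
    tiles$age <- tiles$age + 1
    expect_lt(abs(sum(tiles$area) - 1), 1e-12)
    expect_lt(abs(standcycle:::tile_total_carbon(tiles) + r$fire_co2 -
                    before), 1e-10)
    expect_lte(standcycle:::n_tiles(tiles), 12)
  }
})

test_that("monthly disaggregation preserves the annual burned fraction", {
  # uniform weights spread evenly
  expect_equal(disaggregate_burn(0.12, rep(1, 12)), rep(0.01, 12))
  # all mass in one month
  w <- rep(0, 12); w[7] <- 3
  m <- disaggregate_burn(0.05, w)
  expect_equal(m[7], 0.05)
  expect_equal(sum(m[-7]), 0)
  # random weights: closure to float precision
  set.seed(2)
  for (i in 1:200) {
    w <- runif(12)
    m <- disaggregate_burn(0.05, w)
    expect_lt(abs(sum(m) - 0.05), 1e-15)
  }
  expect_error(disaggregate_burn(0.1, rep(0, 12)), "all zero")
})

test_that("tile set validation catches malformed inputs", {
  expect_error(tile_set(c(0.5, 0.6), c(1, 2),
                        matrix(0, 8, 2,
                               dimnames = list(standcycle:::POOL_NAMES,
                                               NULL))),
               "sum to 1")
  expect_error(tile_set(c(0, 1), c(1, 2),
                        matrix(0, 8, 2,
                               dimnames = list(standcycle:::POOL_NAMES,
                                               NULL))),
               "> 0")
})
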