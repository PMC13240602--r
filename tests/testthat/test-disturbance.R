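test_that("fire partitioning reproduces the printed tissue fractions", {
  # unit green leaf on a woody needleleaf tile
  r <- partition_fire(carbon_pools(green_leaf = 1), "needleleaf")
  expect_equal(r$co2, 0.67)
  expect_equal(r$litter_gain, 0.32)
  expect_equal(r$pools[["green_leaf"]], 0.01, tolerance = 1e-12)
  # two units of needleleaf stem
  r <- partition_fire(carbon_pools(stem = 2), "needleleaf")
  expect_equal(r$co2, 0.33)
  expect_equal(r$litter_gain, 1.66)
  expect_equal(r$pools[["stem"]], 0.01, tolerance = 1e-12)
  # broadleaf stem and nonwoody green leaf use their own pairs
  expect_equal(partition_fire(carbon_pools(stem = 1), "broadleaf")$co2, 0.125)
  expect_equal(partition_fire(carbon_pools(green_leaf = 1), "nonwoody")$co2,
               0.82)
  # brown leaf is PFT-invariant
  expect_equal(partition_fire(carbon_pools(brown_leaf = 1), "broadleaf")$co2,
               0.90)
  # empty input
  r <- partition_fire(carbon_pools(), "needleleaf")
  expect_equal(r$co2, 0)
  expect_equal(r$litter_gain, 0)
})

test_that("fire conserves carbon exactly and is linear in pool mass", {
  set.seed(12)
  for (i in 1:20) {
    pools <- carbon_pools(green_leaf = runif(1), brown_leaf = runif(1),
                          stem = 4 * runif(1), root = 2 * runif(1),
                          litter = 3 * runif(1), soil = 8 * runif(1))
    r <- partition_fire(pools, sample(c("needleleaf", "broadleaf"), 1))
    expect_equal(total_carbon(r$pools) + r$co2, total_carbon(pools),
                 tolerance = 1e-12)
    # linearity: f(a * pools) = a * f(pools)
    a <- runif(1, 0.1, 3)
    scaled <- carbon_pools()
    scaled[] <- unclass(pools) * a
    r2 <- partition_fire(scaled, "needleleaf")
    r1 <- partition_fire(pools, "needleleaf")
    expect_equal(r2$co2, a * r1$co2, tolerance = 1e-12)
    expect_equal(unclass(r2$pools), unclass(r1$pools) * a, tolerance = 1e-12)
  }
})

test_that("default fire table orders stem vs leaf fates as printed", {
  p <- carbon_pools(green_leaf = 1, stem = 1)
  r <- partition_fire(p, "needleleaf")
  tab <- fire_partition_table()
  # stem: more litter than CO2; green leaf: more CO2 than litter
  expect_gt(tab$stem_needleleaf[2], tab$stem_needleleaf[1])
  expect_gt(tab$green_leaf_woody[1], tab$green_leaf_woody[2])
})

test_that("fire table rejects fractions summing above one", {
  expect_error(fire_partition_table(green_leaf_woody = c(0.8, 0.3)),
               "sum above 1")
  expect_error(fire_partition_table(litter_combust = 1.2), "\\[0, 1\\]")
})

test_that("harvest routes stem to products and residues to litter", {
  pools <- carbon_pools(green_leaf = 0.5, brown_leaf = 0.1, stem = 1,
                        root = 0.8, litter = 2, soil = 5)
  r <- apply_harvest(pools)
  expect_equal(r$product_transfer, 0.85)
  expect_equal(r$pools[["products_short"]], 0.34)
  expect_equal(r$pools[["products_long"]], 0.51)
  expect_equal(r$residue_litter, 0.15 + 0.5 + 0.1 + 0.8)
  expect_equal(r$pools[["litter"]], 2 + 0.15 + 0.5 + 0.1 + 0.8)
  # conservation and no atmospheric flux
  expect_equal(total_carbon(r$pools), total_carbon(pools), tolerance = 1e-12)
  # zero stem -> zero transfer
  expect_equal(apply_harvest(carbon_pools(root = 1))$product_transfer, 0)
})

test_that("product decay matches the closed-form exponential", {
  # rate 0: nothing happens
  r <- decay_products(1, 2, c(0, 0))
  expect_equal(r$emission, 0)
  expect_equal(r$products_short, 1)
  # rate log(2): half-life of one year
  r <- decay_products(1, 0, c(log(2), 0))
  expect_equal(r$products_short, 0.5, tolerance = 1e-12)
  expect_equal(r$emission, 0.5, tolerance = 1e-12)
  # conservation for arbitrary rates
  r <- decay_products(0.7, 1.3, c(0.31, 0.017))
  expect_equal((0.7 - r$products_short) + (1.3 - r$products_long),
               r$emission, tolerance = 1e-15)
  expect_error(decay_products(1, 1, c(-0.1, 0)), ">= 0")
})
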