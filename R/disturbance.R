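#' Partition a burned tile's carbon into CO2, litter, and survivors
#'
#' Applies per-tissue combustion/litter fractions to the pools of a tile hit
#' by stand-replacing fire. For each live tissue a fraction goes to the
#' atmosphere as CO2, a fraction to litter, and the small residual stays as
#' live carbon seeding the new age-0 tile. Killed roots go to litter (no
#' below-ground combustion by default); a fraction of the litter and soil
#' pools also combusts. Wood-product pools are untouched by fire. Carbon is
#' conserved exactly: input total = surviving total + CO2.
#'
#' @param pools A [carbon_pools] state for the burned area (per m^2 of that
#'   area).
#' @param pft_class `"needleleaf"`, `"broadleaf"` or `"nonwoody"`; selects the
#'   green-leaf and stem fraction pairs.
#' @param table A [fire_partition_table()].
#' @return List with `pools` (surviving state, litter gains included),
#'   `co2` (kg C m^-2 released) and `litter_gain` (kg C m^-2 transferred
#'   into the litter pool).
#' @examples
#' p <- carbon_pools(green_leaf = 1)
#' partition_fire(p, "needleleaf")$co2  # 0.67
#' @export
partition_fire <- function(pools, pft_class = c("needleleaf", "broadleaf",
                                                "nonwoody"),
                           table = fire_partition_table()) {
  pft_class <- match.arg(pft_class)
  validate_pools(pools)

  gl <- if (pft_class == "nonwoody") table$green_leaf_nonwoody else
    table$green_leaf_woody
  st <- switch(pft_class,
               needleleaf = table$stem_needleleaf,
               broadleaf = table$stem_broadleaf,
               # nonwoody PFTs carry no stem; fractions are irrelevant but
               # the needleleaf pair is used if mass is present
               nonwoody = table$stem_needleleaf)

  co2 <- pools[["green_leaf"]] * gl[1] +
    pools[["brown_leaf"]] * table$brown_leaf[1] +
    pools[["stem"]] * st[1] +
    pools[["root"]] * table$root[1] +
    pools[["litter"]] * table$litter_combust +
    pools[["soil"]] * table$soil_combust

  litter_gain <- pools[["green_leaf"]] * gl[2] +
    pools[["brown_leaf"]] * table$brown_leaf[2] +
    pools[["stem"]] * st[2] +
    pools[["root"]] * table$root[2]

  out <- pools
  out[["green_leaf"]] <- pools[["green_leaf"]] * (1 - sum(gl))
  out[["brown_leaf"]] <- pools[["brown_leaf"]] * (1 - sum(table$brown_leaf))
  out[["stem"]] <- pools[["stem"]] * (1 - sum(st))
  out[["root"]] <- pools[["root"]] * (1 - sum(table$root))
  out[["litter"]] <- pools[["litter"]] * (1 - table$litter_combust) + litter_gain
  out[["soil"]] <- pools[["soil"]] * (1 - table$soil_combust)

  list(pools = out, co2 = unname(co2), litter_gain = unname(litter_gain))
}

#' Apply stand-replacing wood harvest to a tile
#'
#' Stem carbon is split between the harvested-wood product pools and
#' logging-residue litter; all leaf and root mass is transferred to litter.
#' Harvest is an internal transfer: no carbon reaches the atmosphere here
#' (emissions occur later through [decay_products()]). Conservation is exact.
#'
#' @param pools A [carbon_pools] state for the harvested area.
#' @param params A [harvest_params()].
#' @return List with `pools` (post-harvest state), `product_transfer`
#'   (kg C m^-2 moved into product pools) and `residue_litter` (kg C m^-2
#'   moved into litter).
#' @export
apply_harvest <- function(pools, params = harvest_params()) {
  validate_pools(pools)
  stem <- pools[["stem"]]
  removed <- stem * params$stem_to_products
  residue <- stem - removed +
    pools[["green_leaf"]] + pools[["brown_leaf"]] + pools[["root"]]

  out <- pools
  out[["green_leaf"]] <- 0
  out[["brown_leaf"]] <- 0
  out[["stem"]] <- 0
  out[["root"]] <- 0
  out[["litter"]] <- pools[["litter"]] + residue
  out[["products_short"]] <- pools[["products_short"]] +
    removed * params$product_split[["short"]]
  out[["products_long"]] <- pools[["products_long"]] +
    removed * params$product_split[["long"]]

  list(pools = out, product_transfer = unname(removed),
       residue_litter = unname(residue))
}

#' First-order decay of harvested-wood product pools
#'
#' Products decay to the atmosphere with the exact exponential
#' discretization over one annual step: the emission from a pool with rate k
#' is `pool * (1 - exp(-k))`, so a rate of `log(2)` halves the pool in one
#' year. Conservation is exact: pool change + emission = 0.
#'
#' @param products_short,products_long Pool masses, kg C m^-2.
#' @param rates Length-2 decay rates `c(short, long)`, yr^-1.
#' @return List with updated `products_short`, `products_long` and the total
#'   `emission` (kg C m^-2 yr^-1).
#' @export
decay_products <- function(products_short, products_long,
                           rates = harvest_params()$decay_rates) {
  if (any(rates < 0)) stop("product decay rates must be >= 0")
  f <- exp(-rates)
  new_s <- products_short * f[[1]]
  new_l <- products_long * f[[2]]
  emission <- (products_short - new_s) + (products_long - new_l)
  list(products_short = new_s, products_long = new_l,
       emission = emission)
}
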