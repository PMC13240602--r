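#' Dynamic age-class tile sets
#'
#' A tile set represents the sub-cell age structure of one grid cell: each
#' tile is an age cohort with an area fraction, an age (years since
#' stand-replacing disturbance) and its own carbon pools. Area fractions sum
#' to 1. Disturbance splits area off into a new age-0 tile
#' ([split_tiles()]); [merge_tiles()] caps the cohort count (default 12
#' tiles) by combining the most similar ages.
#'
#' @param area Numeric vector of positive area fractions summing to 1.
#' @param age Integer-ish ages, years since disturbance, same length.
#' @param pools An 8 x n matrix of pool states (rows named as in
#'   [carbon_pools()]), or a single `carbon_pools` vector when n = 1.
#' @return Object of class `tile_set`: list with `area`, `age`, `pools`.
#' @export
tile_set <- function(area = 1, age = 0, pools = carbon_pools()) {
  if (is.null(dim(pools))) pools <- matrix(unclass(pools), nrow = 8,
                                           dimnames = list(POOL_NAMES, NULL))
  ts <- list(area = as.numeric(area), age = as.numeric(age), pools = pools)
  validate_tile_set(ts)
  class(ts) <- "tile_set"
  ts
}

validate_tile_set <- function(ts) {
  n <- length(ts$area)
  if (length(ts$age) != n || ncol(ts$pools) != n)
    stop("tile set fields have inconsistent lengths")
  if (any(ts$area <= 0)) stop("tile area fractions must be > 0")
  if (abs(sum(ts$area) - 1) > 1e-9)
    stop("tile area fractions must sum to 1 (got ", sum(ts$area), ")")
  invisible(ts)
}

n_tiles <- function(tiles) length(tiles$area)

tile_total_carbon <- function(tiles) {
  sum(tiles$area * colSums(tiles$pools))
}

#' @export
print.tile_set <- function(x, ...) {
  cat(sprintf("tile set: %d tile(s), total area %.6f, total C %.4f kg m-2\n",
              n_tiles(x), sum(x$area), tile_total_carbon(x)))
  df <- data.frame(area = round(x$area, 4), age = x$age,
                   agb = round(colSums(x$pools[c("green_leaf", "brown_leaf",
                                                 "stem"), , drop = FALSE]), 3))
  print(df)
  invisible(x)
}

#' Split tiles for this year's fire and harvest
#'
#' Removes the disturbed area fraction from the existing tiles (drawn
#' proportionally from all tiles by default, or oldest-first), routes the
#' burned share through [partition_fire()] and the harvested share through
#' [apply_harvest()], and pools the disturbed area into a single new age-0
#' tile. Area and carbon are conserved exactly; the fire CO2 release and the
#' harvest transfer to product pools are returned as cell-level fluxes
#' (kg C per m^2 of the whole cell).
#'
#' @param tiles A [tile_set()].
#' @param burned_frac,harvest_frac Annual disturbed area fractions of the
#'   cell; their sum must not exceed 1.
#' @param pft_class Passed to [partition_fire()].
#' @param fire_table A [fire_partition_table()].
#' @param harvest A [harvest_params()].
#' @param draw `"proportional"` (default) or `"oldest"`: where the disturbed
#'   area is taken from.
#' @return List with `tiles` (new tile set), `fire_co2`, `harvest_removal`
#'   (transfer into product pools) and `fire_litter` (kg C m^-2 cell-level).
#' @export
split_tiles <- function(tiles, burned_frac, harvest_frac = 0,
                        pft_class = "needleleaf",
                        fire_table = fire_partition_table(),
                        harvest = harvest_params(),
                        draw = c("proportional", "oldest")) {
  draw <- match.arg(draw)
  d <- burned_frac + harvest_frac
  if (d > 1 + 1e-12)
    stop("disturbed fraction ", d, " exceeds available area")
  if (d <= 0)
    return(list(tiles = tiles, fire_co2 = 0, harvest_removal = 0,
                fire_litter = 0))

  if (draw == "proportional") {
    # proportional draw: disturbed composition is the area-weighted mean state
    w <- tiles$area / sum(tiles$area)
    pbar <- as.numeric(tiles$pools %*% w)
    area_left <- tiles$area * (1 - d)
    age_left <- tiles$age
    pools_left <- tiles$pools
  } else {
    ord <- order(tiles$age, decreasing = TRUE)
    need <- d
    take <- numeric(n_tiles(tiles))
    for (i in ord) {
      got <- min(tiles$area[i], need)
      take[i] <- got
      need <- need - got
      if (need <= 1e-15) break
    }
    pbar <- as.numeric(tiles$pools %*% (take / sum(take)))
    area_left <- tiles$area - take
    age_left <- tiles$age
    pools_left <- tiles$pools
  }
  names(pbar) <- POOL_NAMES

  new_pools <- numeric(8)
  names(new_pools) <- POOL_NAMES
  fire_co2 <- 0
  harvest_removal <- 0
  fire_litter <- 0
  pb <- carbon_pools()
  pb[POOL_NAMES] <- pbar[POOL_NAMES]
  if (burned_frac > 0) {
    fr <- partition_fire(pb, pft_class, fire_table)
    new_pools <- new_pools + burned_frac * unclass(fr$pools)
    fire_co2 <- burned_frac * fr$co2
    fire_litter <- burned_frac * fr$litter_gain
  }
  if (harvest_frac > 0) {
    hv <- apply_harvest(pb, harvest)
    new_pools <- new_pools + harvest_frac * unclass(hv$pools)
    harvest_removal <- harvest_frac * hv$product_transfer
  }
  new_pools <- new_pools / d

  keep <- area_left > 1e-14
  area <- c(area_left[keep], d)
  age <- c(age_left[keep], 0)
  pools <- cbind(pools_left[, keep, drop = FALSE],
                 matrix(new_pools, nrow = 8))
  rownames(pools) <- POOL_NAMES
  out <- list(area = area, age = age, pools = pools)
  class(out) <- "tile_set"
  list(tiles = out, fire_co2 = fire_co2, harvest_removal = harvest_removal,
       fire_litter = fire_litter)
}

#' Merge tiles down to the configured maximum
#'
#' While the tile count exceeds `max_tiles`, the pair of tiles with the
#' smallest age difference (ties broken by smallest combined area) is merged:
#' areas add, pools are area-weighted means, and the merged age is the
#' area-weighted mean age rounded to the nearest year. Area and carbon are
#' conserved exactly.
#'
#' @param tiles A [tile_set()].
#' @param max_tiles Maximum cohort count (default 12).
#' @return A [tile_set()] with at most `max_tiles` tiles.
#' @export
merge_tiles <- function(tiles, max_tiles = 12) {
  while (n_tiles(tiles) > max_tiles) {
    ord <- order(tiles$age)
    a <- tiles$age[ord]
    gaps <- diff(a)
    cand <- which(gaps == min(gaps))
    if (length(cand) > 1) {
      comb <- tiles$area[ord][cand] + tiles$area[ord][cand + 1]
      cand <- cand[which.min(comb)]
    }
    i <- ord[cand]
    j <- ord[cand + 1]
    ai <- tiles$area[i]; aj <- tiles$area[j]
    anew <- ai + aj
    pnew <- (tiles$pools[, i] * ai + tiles$pools[, j] * aj) / anew
    agenew <- round((tiles$age[i] * ai + tiles$age[j] * aj) / anew)
    keep <- setdiff(seq_len(n_tiles(tiles)), c(i, j))
    tiles <- structure(list(
      area = c(tiles$area[keep], anew),
      age = c(tiles$age[keep], agenew),
      pools = cbind(tiles$pools[, keep, drop = FALSE],
                    matrix(pnew, nrow = 8,
                           dimnames = list(POOL_NAMES, NULL)))),
      class = "tile_set")
  }
  tiles
}

#' Disaggregate an annual burned fraction to months
#'
#' Distributes an annual burned-area fraction over 12 months in proportion
#' to a monthly climatology. The monthly values sum to the annual fraction
#' exactly (up to float rounding). Reporting-only: the pool model is annual.
#'
#' @param annual_frac Annual burned fraction.
#' @param monthly_weights 12 non-negative weights, not all zero.
#' @return Numeric vector of 12 monthly fractions.
#' @export
disaggregate_burn <- function(annual_frac,
                              monthly_weights = default_burn_climatology()) {
  if (length(monthly_weights) != 12L || any(monthly_weights < 0))
    stop("monthly_weights must be 12 non-negative values")
  s <- sum(monthly_weights)
  if (s == 0) stop("monthly_weights are all zero")
  annual_frac * monthly_weights / s
}
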