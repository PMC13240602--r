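#' CO2 fertilization response with downregulation
#'
#' Multiplicative factor on GPP representing the damped response of
#' photosynthesis to rising atmospheric CO2 under progressive nutrient
#' limitation: `1 + gamma * log(c / c0)`, clipped below at zero. `gamma = 0`
#' switches fertilization off; `gamma = 1` gives the full logarithmic
#' response; the default parameterization uses `gamma = 0.5`.
#'
#' @param c Atmospheric CO2, ppm (> 0).
#' @param c0 Reference CO2 (the spin-up concentration), ppm (> 0).
#' @param gamma Downregulation parameter, >= 0.
#' @return Numeric factor >= 0, vectorized over `c`.
#' @examples
#' co2_response(420, 289, 0.5)  # about 1.187
#' @export
co2_response <- function(c, c0, gamma) {
  if (any(c <= 0) || c0 <= 0)
    stop("CO2 concentrations must be positive")
  if (gamma < 0) stop("gamma must be >= 0")
  pmax(0, 1 + gamma * log(c / c0))
}

# Vectorized annual update of a matrix of tile pool states (8 x n).
# Returns updated pools plus per-tile fluxes (kg C m^-2 yr^-1 of tile area).
step_tiles <- function(pools, ages, params, tair_anomaly, co2,
                       decay_rates = c(short = 1 / 5, long = 1 / 50)) {
  p <- params
  rs <- p$respiration_scale
  ft <- p$q10^(tair_anomaly / 10)
  fage <- 1 - exp(-pmax(ages, 0) / p$tau_rec)
  gpp <- p$gpp_max * p$vcmax_scale * fage * exp(p$beta_gpp * tair_anomaly) *
    co2_response(co2, p$c0, p$gamma)

  gl <- pools["green_leaf", ]; bl <- pools["brown_leaf", ]
  st <- pools["stem", ]; rt <- pools["root", ]
  li <- pools["litter", ]; so <- pools["soil", ]
  ps <- pools["products_short", ]; pl <- pools["products_long", ]

  rm <- rs * ft * (p$rm_rates[["green_leaf"]] * gl +
                   p$rm_rates[["brown_leaf"]] * bl +
                   p$rm_rates[["stem"]] * st +
                   p$rm_rates[["root"]] * rt)
  rg <- rs * p$rg_frac * pmax(gpp - rm, 0)
  ra <- rm + rg
  npp <- gpp - ra

  t_gl <- gl / p$tau_leaf
  t_bl <- bl / p$tau_brown
  t_st <- st / p$tau_stem
  t_rt <- rt / p$tau_root

  d_litter <- rs * p$k_litter * ft * li
  rh_litter <- (1 - p$humification) * d_litter
  soil_gain <- p$humification * d_litter
  rh_soil <- rs * p$k_soil * ft * so
  rh <- rh_litter + rh_soil

  dec <- decay_products(ps, pl, decay_rates)

  # positive NPP is allocated by the fixed fractions; a carbon deficit
  # (negative NPP, e.g. right after stand-replacing disturbance) is drawn
  # from the live pools in proportion to their mass so no pool overdraws
  live <- gl + st + rt
  neg <- npp < 0 & live > 0
  w_l <- ifelse(neg, gl / pmax(live, 1e-300), p$alloc[["leaf"]])
  w_s <- ifelse(neg, st / pmax(live, 1e-300), p$alloc[["stem"]])
  w_r <- ifelse(neg, rt / pmax(live, 1e-300), p$alloc[["root"]])

  out <- pools
  out["green_leaf", ] <- gl + w_l * npp - t_gl
  out["brown_leaf", ] <- bl + t_gl - t_bl
  out["stem", ] <- st + w_s * npp - t_st
  out["root", ] <- rt + w_r * npp - t_rt
  out["litter", ] <- li + t_bl + t_st + t_rt - d_litter
  out["soil", ] <- so + soil_gain - rh_soil
  out["products_short", ] <- dec$products_short
  out["products_long", ] <- dec$products_long

  if (any(out < -1e-12)) {
    bad <- POOL_NAMES[which(apply(out < -1e-12, 1, any))]
    stop("internal error: negative pool after update: ",
         paste(bad, collapse = ", "))
  }
  out[out < 0] <- 0  # remove float dust only; real negatives error above

  list(pools = out,
       gpp = gpp, ra = ra, rh = rh, npp = npp,
       product_emission = dec$emission)
}

#' Advance one tile by one year
#'
#' The annual carbon-pool update for a single age cohort: GPP from the age,
#' climate and CO2 responses; maintenance and growth respiration; allocation
#' of NPP to leaf, stem and root; tissue turnover to litter; litter
#' decomposition with humification to soil; soil decomposition; and
#' first-order product-pool decay. The returned flux entry satisfies the
#' ledger identities `er = ra + rh`, `nep = gpp - er`,
#' `nbp = nep - fire_co2 - product_emission`, and the pool change over the
#' year equals NBP exactly (fire CO2 is zero here; fire happens in
#' [split_tiles()]).
#'
#' @param pools A [carbon_pools] state.
#' @param age Years since disturbance at the start of the year.
#' @param params A [pft_params()].
#' @param tair_anomaly Air-temperature anomaly, deg C.
#' @param co2 Atmospheric CO2, ppm.
#' @param decay_rates Product-pool decay rates, see [decay_products()].
#' @return List with `pools` (end-of-year state), `age` (incremented) and
#'   `fluxes` (named vector: gpp, npp, ra, rh, er, nep, fire_co2,
#'   harvest_removal, product_emission, nbp; kg C m^-2 yr^-1).
#' @export
step_year <- function(pools, age, params, tair_anomaly, co2,
                      decay_rates = harvest_params()$decay_rates) {
  validate_pools(pools)
  if (!is.finite(tair_anomaly) || !is.finite(co2))
    stop("forcing for step_year contains non-finite values")
  mat <- matrix(unclass(pools), nrow = 8, dimnames = list(POOL_NAMES, NULL))
  st <- step_tiles(mat, age, params, tair_anomaly, co2, decay_rates)
  out <- carbon_pools()
  out[POOL_NAMES] <- st$pools[, 1]
  gpp <- unname(st$gpp); ra <- unname(st$ra); rh <- unname(st$rh)
  pe <- unname(st$product_emission)
  fl <- c(gpp = gpp, npp = unname(st$npp), ra = ra, rh = rh,
          er = ra + rh, nep = gpp - ra - rh,
          fire_co2 = 0, harvest_removal = 0, product_emission = pe,
          nbp = gpp - ra - rh - pe)
  list(pools = out, age = age + 1, fluxes = fl)
}

#' Spin a stand up to carbon equilibrium
#'
#' Repeats the first `loop_years` years of a cell's climate with CO2 held at
#' the reference concentration `params$c0` and no disturbance, until the
#' total-carbon change per cycle falls below `tol`. Deterministic; errors if
#' equilibrium is not reached within `max_cycles`, naming the
#' slowest-converging pool.
#'
#' @param params A [pft_params()]; `params$c0` is the held CO2.
#' @param tair_anomaly Vector of at least `loop_years` annual temperature
#'   anomalies (the first `loop_years` values are looped).
#' @param loop_years Length of the repeated climate cycle (default 25).
#' @param tol Convergence tolerance, kg C m^-2 total-carbon change per
#'   cycle (default 1e-4). `Inf` returns after a single cycle.
#' @param max_cycles Cycle cap (default 400).
#' @param init Optional starting state (default: bare ground, age 0).
#' @return List with `pools` (equilibrium [carbon_pools]), `age`, `cycles`
#'   used and `delta` (last per-cycle total-carbon change).
#' @export
run_spinup <- function(params, tair_anomaly, loop_years = 25,
                       tol = 1e-4, max_cycles = 400, init = NULL) {
  if (length(tair_anomaly) < loop_years)
    stop("need at least ", loop_years, " years of climate to loop")
  cyc <- tair_anomaly[seq_len(loop_years)]
  pools <- if (is.null(pools <- init$pools)) carbon_pools() else pools
  age <- if (is.null(init)) 0 else init$age
  mat <- matrix(unclass(pools), nrow = 8, dimnames = list(POOL_NAMES, NULL))
  for (cycle in seq_len(max_cycles)) {
    before <- mat[, 1]
    for (k in seq_len(loop_years)) {
      stp <- step_tiles(mat, age, params, cyc[k], params$c0)
      mat <- stp$pools
      age <- age + 1
    }
    delta <- sum(mat[, 1]) - sum(before)
    if (abs(delta) < tol) {
      out <- carbon_pools()
      out[POOL_NAMES] <- mat[, 1]
      return(list(pools = out, age = age, cycles = cycle, delta = delta))
    }
  }
  slowest <- POOL_NAMES[which.max(abs(mat[, 1] - before))]
  stop("spin-up did not converge within ", max_cycles,
       " cycles; slowest pool: ", slowest)
}

#' Run protocols
#'
#' Era boundaries for a simulation. The `"domain"` protocol spins up under
#' conditions of its first forcing year (nominally 1750), loops the first
#' 25 years of climate until `loop_until` (1900) while CO2 varies, then runs
#' fully transient. The `"site"` protocol is the same structure anchored at
#' 1700 and is used for single-cell factual/counterfactual runs without
#' dynamic tiling.
#'
#' @param type `"domain"` or `"site"`.
#' @param spinup_year Year whose CO2 is the spin-up reference (`c0`).
#' @param loop_until First year of fully transient climate.
#' @param loop_years Length of the repeated early-climate cycle.
#' @return List of class `sim_protocol`.
#' @export
sim_protocol <- function(type = c("domain", "site"),
                         spinup_year = NULL, loop_until = 1900,
                         loop_years = 25) {
  type <- match.arg(type)
  if (is.null(spinup_year))
    spinup_year <- if (type == "domain") 1750 else 1700
  if (spinup_year > loop_until) stop("era boundaries out of order")
  structure(list(type = type, spinup_year = spinup_year,
                 loop_until = loop_until, loop_years = loop_years),
            class = "sim_protocol")
}

#' Driver switches for factorial runs
#'
#' Controls which drivers vary during the transient run. Holding a driver at
#' `"spinup"` keeps it at its spin-up state for the whole run (climate:
#' looped early cycle; CO2: reference concentration). Disturbance can be on,
#' off, or suppressed before a boundary year (`from`), which isolates the
#' legacy of early disturbance.
#'
#' @param climate,co2 `"transient"` or `"spinup"`.
#' @param disturbance `"on"` or `"off"`.
#' @param disturbance_from Optional year; disturbance before it is zeroed.
#' @return List of class `driver_spec`.
#' @export
driver_spec <- function(climate = c("transient", "spinup"),
                        co2 = c("transient", "spinup"),
                        disturbance = c("on", "off"),
                        disturbance_from = NULL) {
  structure(list(climate = match.arg(climate), co2 = match.arg(co2),
                 disturbance = match.arg(disturbance),
                 disturbance_from = disturbance_from),
            class = "driver_spec")
}

#' Simulate the carbon cycle of a cell ensemble
#'
#' The central entry point: spins each cell up to equilibrium (unless an
#' initial state is supplied), then runs the transient protocol year by
#' year, applying fire and harvest through dynamic age-class tiling,
#' stepping every tile, and merging tiles back to the cap. Carbon closure is
#' audited every cell-year (pool change must equal NBP) and over the whole
#' run; the maximum residual is stored on the returned object.
#'
#' @param params A [pft_params()]. Its `c0` is overwritten with the CO2 of
#'   the protocol's spin-up year as read from the forcing.
#' @param forcing A [carbon_forcing()] covering the run years.
#' @param protocol A [sim_protocol()].
#' @param drivers A [driver_spec()].
#' @param init Optional named list (by cell) of spin-up states, as returned
#'   by [run_spinup()]; skips the internal spin-up.
#' @param tiling Use dynamic tiling (`TRUE`, domain runs) or a single tile
#'   (`FALSE`, site runs; 100% disturbances still reset the stand).
#' @param max_tiles Tile cap per cell (default 12).
#' @param pft_class,fire_table,harvest Disturbance configuration, see
#'   [partition_fire()] and [apply_harvest()].
#' @param draw Disturbed-area draw rule, see [split_tiles()].
#' @param spinup_tol,spinup_max_cycles Passed to [run_spinup()].
#' @return Object of class `carbon_sim`: per-year per-cell flux matrices
#'   (`$fluxes`, kg C m^-2 yr^-1), `$agb` and `$total_c` state matrices,
#'   tile counts, the spin-up states, parameters and closure diagnostics.
#' @seealso [flux_ledger()], [national_summary()], [attribute_nbp()]
#' @export
carbon_sim <- function(params = pft_params(), forcing,
                       protocol = sim_protocol("domain"),
                       drivers = driver_spec(),
                       init = NULL, tiling = TRUE, max_tiles = 12,
                       pft_class = "needleleaf",
                       fire_table = fire_partition_table(),
                       harvest = harvest_params(),
                       draw = "proportional",
                       spinup_tol = 1e-4, spinup_max_cycles = 400) {
  if (!inherits(forcing, "carbon_forcing"))
    forcing <- carbon_forcing(forcing)
  cells <- unique(forcing$cell)
  years <- sort(unique(forcing$year))
  if (any(diff(years) != 1)) stop("forcing years must be consecutive")
  y0 <- years[1]
  ny <- length(years)
  loop_n <- protocol$loop_years
  if (ny < loop_n) stop("forcing must cover at least one climate loop cycle")

  co2_series <- forcing$co2_ppm[match(years, forcing$year)]
  ref_year <- max(min(years), protocol$spinup_year)
  c0 <- co2_series[ref_year - y0 + 1]
  params$c0 <- c0

  flux_names <- c("gpp", "npp", "ra", "rh", "er", "nep", "fire_co2",
                  "harvest_removal", "product_emission", "nbp")
  fx <- lapply(flux_names, function(i)
    matrix(0, ny, length(cells), dimnames = list(years, cells)))
  names(fx) <- flux_names
  agb_m <- matrix(0, ny, length(cells), dimnames = list(years, cells))
  tc_m <- agb_m
  ntile_m <- agb_m
  pool_state <- array(0, c(8, ny, length(cells)),
                      dimnames = list(POOL_NAMES, years, cells))
  co2_used <- if (drivers$co2 == "transient") co2_series else
    rep(c0, ny)
  max_resid <- 0
  spin_states <- vector("list", length(cells))
  names(spin_states) <- as.character(cells)
  final_tiles <- spin_states

  for (ci in seq_along(cells)) {
    fc <- forcing[forcing$cell == cells[ci], ]
    tair <- fc$tair_anomaly[match(years, fc$year)]
    bf <- fc$burned_frac[match(years, fc$year)]
    hf <- fc$harvest_frac[match(years, fc$year)]

    sp <- if (!is.null(init)) init[[as.character(cells[ci])]] else
      run_spinup(params, tair, loop_n, spinup_tol, spinup_max_cycles)
    spin_states[[ci]] <- sp
    tiles <- tile_set(1, sp$age, sp$pools)

    for (yi in seq_len(ny)) {
      y <- years[yi]
      looped <- drivers$climate == "spinup" || y < protocol$loop_until
      ti <- if (looped) ((y - y0) %% loop_n) + 1 else yi
      dT <- tair[ti]
      co2_y <- if (drivers$co2 == "transient") co2_series[yi] else c0

      b <- bf[yi]; h <- hf[yi]
      if (drivers$disturbance == "off") b <- h <- 0
      if (!is.null(drivers$disturbance_from) && y < drivers$disturbance_from)
        b <- h <- 0

      c_before <- tile_total_carbon(tiles)
      fire_co2 <- 0; harvest_removal <- 0
      if (b + h > 0) {
        spl <- split_tiles(tiles, b, h, pft_class, fire_table, harvest, draw)
        tiles <- spl$tiles
        fire_co2 <- spl$fire_co2
        harvest_removal <- spl$harvest_removal
      }

      stp <- step_tiles(tiles$pools, tiles$age, params, dT, co2_y,
                        harvest$decay_rates)
      tiles$pools <- stp$pools
      tiles$age <- tiles$age + 1
      a <- tiles$area
      gpp <- sum(a * stp$gpp); ra <- sum(a * stp$ra); rh <- sum(a * stp$rh)
      pe <- sum(a * stp$product_emission)
      nep <- gpp - ra - rh
      nbp <- nep - fire_co2 - pe

      if (n_tiles(tiles) > max_tiles && tiling)
        tiles <- merge_tiles(tiles, max_tiles)

      c_after <- tile_total_carbon(tiles)
      resid <- abs((c_after - c_before) - nbp) / max(1, c_after)
      if (resid > max_resid) max_resid <- resid

      fx$gpp[yi, ci] <- gpp; fx$ra[yi, ci] <- ra; fx$rh[yi, ci] <- rh
      fx$npp[yi, ci] <- gpp - ra
      fx$er[yi, ci] <- ra + rh; fx$nep[yi, ci] <- nep
      fx$fire_co2[yi, ci] <- fire_co2
      fx$harvest_removal[yi, ci] <- harvest_removal
      fx$product_emission[yi, ci] <- pe
      fx$nbp[yi, ci] <- nbp
      agb_m[yi, ci] <- sum(tiles$area * colSums(
        tiles$pools[c("green_leaf", "brown_leaf", "stem"), , drop = FALSE]))
      tc_m[yi, ci] <- c_after
      ntile_m[yi, ci] <- n_tiles(tiles)
      pool_state[, yi, ci] <- as.numeric(tiles$pools %*% tiles$area)
    }
    final_tiles[[ci]] <- tiles
  }

  structure(list(years = years, cells = cells, fluxes = fx,
                 agb = agb_m, total_c = tc_m, tile_count = ntile_m,
                 pool_state = pool_state, co2_used = co2_used,
                 spinup = spin_states, final_tiles = final_tiles,
                 params = params, protocol = protocol, drivers = drivers,
                 cell_area = attr(forcing, "cell_area"),
                 max_closure_residual = max_resid),
            class = "carbon_sim")
}

#' Transient run from a supplied equilibrium state
#'
#' Thin wrapper over [carbon_sim()] that requires the initial (spun-up)
#' states rather than computing them, for factorial designs where one
#' spin-up serves many runs.
#'
#' @param init Named list (by cell) of [run_spinup()] states.
#' @inheritParams carbon_sim
#' @param ... Passed to [carbon_sim()].
#' @return A `carbon_sim` object.
#' @export
run_transient <- function(init, params, forcing,
                          protocol = sim_protocol("domain"),
                          drivers = driver_spec(), ...) {
  if (is.null(init)) stop("run_transient requires spun-up initial states")
  carbon_sim(params, forcing, protocol, drivers, init = init, ...)
}

#' Extract the annual flux ledger of a run
#'
#' @param sim A `carbon_sim` object.
#' @param aggregate `"mean"` (area-weighted mean across cells, kg C m^-2
#'   yr^-1; cells have equal nominal area so this is the plain mean),
#'   `"total"` (domain totals, Tg C yr^-1) or `"cell"` (long format).
#' @return Data frame with one row per year (or per cell-year).
#' @export
flux_ledger <- function(sim, aggregate = c("mean", "total", "cell")) {
  aggregate <- match.arg(aggregate)
  fx <- sim$fluxes
  if (aggregate == "cell") {
    out <- do.call(rbind, lapply(seq_along(sim$cells), function(ci) {
      data.frame(year = sim$years, cell = sim$cells[ci],
                 lapply(fx, function(m) m[, ci]))
    }))
    rownames(out) <- NULL
    return(out)
  }
  agg <- lapply(fx, rowMeans)
  out <- data.frame(year = sim$years, agg)
  if (aggregate == "total") {
    area_total <- sim$cell_area * length(sim$cells)
    for (nm in names(fx)) out[[nm]] <- out[[nm]] * area_total * 1e-9  # Tg C
  }
  rownames(out) <- NULL
  out
}
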