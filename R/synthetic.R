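#' Generate synthetic climate and CO2 forcing
#'
#' Seeded generator emulating the statistical structure of a historical
#' reanalysis-style driver at desk scale: per-cell AR(1) interannual
#' temperature anomalies with a linear warming trend switched on at
#' `trend_start`, a unit-mean precipitation index, and a smooth monotone
#' atmospheric CO2 ramp (default 289 to 420 ppm over 1900-2023, held flat at
#' the start value before the ramp). Burned and harvested fractions are zero;
#' use [gen_scenarios()] to fill them.
#'
#' @param years Integer vector of consecutive calendar years.
#' @param n_cells Number of grid cells.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments.
#' @param warming_rate Linear warming, deg C per century, from `trend_start`.
#' @param trend_start First year of the warming trend.
#' @param ar1_phi,ar1_sd AR(1) autocorrelation and innovation sd of the
#'   interannual anomaly (deg C).
#' @param co2_start,co2_end,co2_ramp CO2 endpoints (ppm) and the
#'   `c(start, end)` years of the ramp; quadratic-in-time (accelerating)
#'   growth between them.
#' @param cell_area Passed to [carbon_forcing()].
#' @return A [carbon_forcing()] object.
#' @export
gen_forcing <- function(years, n_cells = 1, seed = 1,
                        warming_rate = 2.0, trend_start = 1970,
                        ar1_phi = 0.6, ar1_sd = 0.5,
                        co2_start = 289, co2_end = 420,
                        co2_ramp = c(1900, 2023),
                        cell_area = NULL) {
  if (!length(years)) stop("years must be non-empty")
  set.seed(seed)
  ny <- length(years)
  trend <- pmax(0, years - trend_start) * warming_rate / 100

  u <- (years - co2_ramp[1]) / (co2_ramp[2] - co2_ramp[1])
  u <- pmin(pmax(u, 0), 1)
  co2 <- co2_start + (co2_end - co2_start) * u^2

  out <- vector("list", n_cells)
  marg_sd <- if (ar1_sd > 0) ar1_sd / sqrt(1 - ar1_phi^2) else 0
  for (ci in seq_len(n_cells)) {
    e <- if (ar1_sd > 0) stats::rnorm(ny, 0, ar1_sd) else numeric(ny)
    x <- numeric(ny)
    x[1] <- if (marg_sd > 0) stats::rnorm(1, 0, marg_sd) else 0
    for (t in seq_len(ny - 1)) x[t + 1] <- ar1_phi * x[t] + e[t + 1]
    out[[ci]] <- data.frame(
      year = years, cell = sprintf("c%03d", ci),
      tair_anomaly = trend + x,
      precip_index = pmax(0.2, stats::rnorm(ny, 1, 0.1)),
      co2_ppm = co2, burned_frac = 0, harvest_frac = 0)
  }
  carbon_forcing(do.call(rbind, out), cell_area = cell_area)
}

#' Specification of the disturbance-scenario ensemble
#'
#' Parameters of the 2 x 2 synthetic disturbance ensemble: a lognormal
#' baseline burned-area fraction, an additive pre-observation-era offset for
#' the "inferred" (stand-age-based, elevated) scenarios, and an additive
#' observation-era offset for the "vector" (vs. raster) record variants.
#' The default fraction scale maps a 400 Mha nominal burnable domain onto
#' area fractions: baseline mean 0.004/yr (about 1.6 Mha/yr), inferred
#' pre-era offset 0.008 (about 3.2 Mha/yr), vector observation-era offset
#' 0.00175 (about 0.7 Mha/yr).
#'
#' @param years Consecutive calendar years the scenarios span.
#' @param n_cells Number of cells.
#' @param burn_mean,burn_sdlog Mean annual burned fraction and lognormal
#'   shape (sd of log) of the baseline draw.
#' @param pre_boundary Boundary year: the pre-era offset applies to years
#'   strictly before it (analogue of 1918).
#' @param inferred_offset Additive pre-era burned-fraction offset of the
#'   inferred scenarios.
#' @param obs_start First year of the observation era (analogue of 1985).
#' @param vector_offset Additive observation-era offset of the vector
#'   variants.
#' @param harvest_mean,harvest_sd Clipped-normal harvest fraction moments.
#' @param seed Integer seed.
#' @return List of class `scenario_spec`.
#' @export
scenario_spec <- function(years = 1750:2023, n_cells = 6,
                          burn_mean = 0.004, burn_sdlog = 0.8,
                          pre_boundary = 1918, inferred_offset = 0.008,
                          obs_start = 1985, vector_offset = 0.00175,
                          harvest_mean = 0.002, harvest_sd = 0.001,
                          seed = 1) {
  if (inferred_offset < 0 || vector_offset < 0)
    stop("scenario offsets must be >= 0")
  structure(list(years = years, n_cells = n_cells, burn_mean = burn_mean,
                 burn_sdlog = burn_sdlog, pre_boundary = pre_boundary,
                 inferred_offset = inferred_offset, obs_start = obs_start,
                 vector_offset = vector_offset, harvest_mean = harvest_mean,
                 harvest_sd = harvest_sd, seed = seed),
            class = "scenario_spec")
}

#' Generate the four-member disturbance-scenario ensemble
#'
#' Builds the 2 x 2 ensemble {mean, inferred} x {raster, vector} on top of a
#' climate forcing. All four scenarios share one baseline burned-fraction
#' realization (lognormal, right-skewed, iid across cell-years) and one
#' harvest realization; the "inferred" members add a constant offset before
#' the pre-observation boundary, and the "vector" members add a smaller
#' constant offset during the observation era. Scenarios are therefore
#' identical wherever no offset applies. Fractions are clipped to keep
#' burned + harvested within [0, 1] (with a warning if clipping occurs).
#'
#' @param spec A [scenario_spec()].
#' @param forcing Optional [carbon_forcing()] supplying climate and CO2 for
#'   the same years/cells; generated with [gen_forcing()] (seed
#'   `spec$seed`) when omitted.
#' @return Named list of four [carbon_forcing()] objects:
#'   `mean_raster`, `mean_vector`, `inferred_raster`, `inferred_vector`.
#' @export
gen_scenarios <- function(spec = scenario_spec(), forcing = NULL) {
  if (is.null(forcing))
    forcing <- gen_forcing(spec$years, spec$n_cells, seed = spec$seed)
  years <- sort(unique(forcing$year))
  cells <- unique(forcing$cell)
  if (!setequal(years, spec$years))
    stop("forcing years do not match scenario spec years")

  set.seed(spec$seed + 1L)
  n <- nrow(forcing)
  mu <- log(spec$burn_mean) - spec$burn_sdlog^2 / 2
  base_burn <- stats::rlnorm(n, mu, spec$burn_sdlog)
  harv <- pmin(pmax(stats::rnorm(n, spec$harvest_mean, spec$harvest_sd), 0), 1)

  pre <- forcing$year < spec$pre_boundary
  obs <- forcing$year >= spec$obs_start

  variants <- list(
    mean_raster = c(inferred = FALSE, vector = FALSE),
    mean_vector = c(inferred = FALSE, vector = TRUE),
    inferred_raster = c(inferred = TRUE, vector = FALSE),
    inferred_vector = c(inferred = TRUE, vector = TRUE))

  out <- lapply(variants, function(v) {
    b <- base_burn
    if (v[["inferred"]]) b <- b + pre * spec$inferred_offset
    if (v[["vector"]]) b <- b + obs * spec$vector_offset
    over <- b + harv > 1
    if (any(over)) {
      warning("burned + harvest fractions clipped to 1 for ",
              sum(over), " cell-years")
      b[over] <- 1 - harv[over]
    }
    f <- forcing
    f$burned_frac <- pmin(pmax(b, 0), 1)
    f$harvest_frac <- harv
    carbon_forcing(as.data.frame(f),
                   monthly_weights = attr(forcing, "monthly_weights"),
                   cell_area = attr(forcing, "cell_area"))
  })
  out
}

#' Generate pseudo-tower observations from a truth series
#'
#' Adds iid Gaussian noise to a table of true fluxes/biomass, emulating
#' eddy-covariance and inventory observation error in a twin experiment.
#'
#' @param truth Data frame with a `year` column and one column per observed
#'   variable (e.g. `gpp`, `er`, `nep`, `agb`).
#' @param noise_sd Named vector of observation noise standard deviations per
#'   variable; variables absent from it get noise 0.
#' @param seed Integer seed.
#' @return Data frame of the same shape with noisy values.
#' @export
gen_tower_obs <- function(truth, noise_sd, seed = 1) {
  if (any(noise_sd < 0)) stop("noise_sd must be >= 0")
  set.seed(seed)
  out <- truth
  vars <- setdiff(names(truth), c("year", "site_id"))
  for (v in vars) {
    sd_v <- if (v %in% names(noise_sd)) noise_sd[[v]] else 0
    if (sd_v > 0) out[[v]] <- truth[[v]] + stats::rnorm(nrow(truth), 0, sd_v)
  }
  out
}
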