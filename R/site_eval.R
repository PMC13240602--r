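#' Mean absolute error
#'
#' @param pred,obs Equal-length numeric series.
#' @return Mean of `abs(pred - obs)`.
#' @export
mae <- function(pred, obs) {
  if (length(pred) != length(obs)) stop("pred and obs must have equal length")
  if (!length(pred)) stop("empty series")
  mean(abs(pred - obs))
}

#' Change in mean absolute error between counterfactual and factual runs
#'
#' `delta_mae = MAE(counterfactual, obs) - MAE(factual, obs)`. Positive
#' values mean the disturbance-aware (factual) run fits the observations
#' better, i.e. representing disturbance improves the model.
#'
#' @param pred_factual,pred_counterfactual,obs Aligned numeric series.
#' @return Numeric scalar in the units of the variable.
#' @export
delta_mae <- function(pred_factual, pred_counterfactual, obs) {
  mae(pred_counterfactual, obs) - mae(pred_factual, obs)
}

#' Run the factual/counterfactual pair for one site
#'
#' Single-cell simulation pair under the site protocol: equilibrium spin-up
#' (CO2 held at the spin-up-year concentration), looped early climate, then
#' a transient run. The factual member imposes one 100% stand-replacing
#' disturbance (fire or harvest) in `disturbance_year`; the counterfactual
#' ignores disturbance entirely. No dynamic tiling is used at the site
#' level. The spin-up is shared between the two members.
#'
#' @param params A [pft_params()].
#' @param forcing Single-cell [carbon_forcing()] (its burned/harvest columns
#'   are overridden).
#' @param disturbance_year Calendar year of the stand-replacing event.
#' @param type `"fire"` or `"harvest"`.
#' @param protocol A [sim_protocol()], default the site protocol.
#' @param ... Passed to [carbon_sim()].
#' @return List with `factual` and `counterfactual` `carbon_sim` objects.
#' @export
run_site_pair <- function(params, forcing, disturbance_year,
                          type = c("fire", "harvest"),
                          protocol = sim_protocol("site"), ...) {
  type <- match.arg(type)
  if (length(unique(forcing$cell)) != 1L)
    stop("site runs take a single-cell forcing")
  if (!disturbance_year %in% forcing$year)
    stop("disturbance_year outside the forcing years")
  f <- as.data.frame(forcing)
  f$burned_frac <- 0
  f$harvest_frac <- 0
  hit <- f$year == disturbance_year
  if (type == "fire") f$burned_frac[hit] <- 1 else f$harvest_frac[hit] <- 1
  f <- carbon_forcing(f, monthly_weights = attr(forcing, "monthly_weights"),
                      cell_area = attr(forcing, "cell_area"))

  fact <- carbon_sim(params, f, protocol,
                     driver_spec(disturbance = "on"), tiling = FALSE, ...)
  cf <- run_transient(fact$spinup, params, f, protocol,
                      driver_spec(disturbance = "off"), tiling = FALSE, ...)
  list(factual = fact, counterfactual = cf)
}

site_series <- function(sim, years, variable) {
  idx <- match(years, sim$years)
  if (anyNA(idx)) stop("requested years outside the simulated span")
  if (variable == "agb") sim$agb[idx, 1] else sim$fluxes[[variable]][idx, 1]
}

#' Twin-experiment site records
#'
#' Generates a synthetic flux-tower network for the factual/counterfactual
#' evaluation: for each site, a single-cell climate forcing is drawn, the
#' factual run (with a known stand-replacing disturbance) provides the truth,
#' pseudo-observations add Gaussian noise, and both the factual and
#' counterfactual predictions are recorded over the observation window. Site
#' ages since disturbance are spread evenly so the set forms a
#' chronosequence.
#'
#' @param n_sites Number of sites.
#' @param params A [pft_params()].
#' @param seed Integer seed (forcing, ages, disturbance types and
#'   observation noise all derive from it).
#' @param obs_years Calendar years of the observation window.
#' @param max_age Oldest time-since-disturbance (at the start of the
#'   observation window) in the network.
#' @param noise_sd Named observation noise sd per variable
#'   (kg C m^-2 yr^-1; AGB kg C m^-2).
#' @param forcing_years Years of each site's forcing record.
#' @return Long data frame of site records: `site_id`, `variable`, `year`,
#'   `observed`, `predicted_factual`, `predicted_counterfactual`,
#'   `disturbance_year`, `disturbance_type`.
#' @export
simulate_site_network <- function(n_sites = 18, params = pft_params(),
                                  seed = 1, obs_years = 2000:2005,
                                  max_age = 140,
                                  noise_sd = c(gpp = 0.08, er = 0.08,
                                               nep = 0.06, agb = 0.4),
                                  forcing_years = 1700:2005) {
  ages <- round(seq(2, max_age, length.out = n_sites))
  types <- rep(c("fire", "harvest"), length.out = n_sites)
  vars <- c("gpp", "er", "nep", "agb")
  rec <- vector("list", n_sites)
  for (s in seq_len(n_sites)) {
    f <- gen_forcing(forcing_years, 1, seed = seed * 1000L + s)
    dist_year <- min(obs_years) - ages[s]
    pair <- run_site_pair(params, f, dist_year, types[s])
    truth <- data.frame(year = obs_years,
                        lapply(stats::setNames(vars, vars), function(v)
                          site_series(pair$factual, obs_years, v)))
    obs <- gen_tower_obs(truth, noise_sd, seed = seed * 2000L + s)
    rec[[s]] <- do.call(rbind, lapply(vars, function(v) {
      data.frame(site_id = sprintf("site%02d", s), variable = v,
                 year = obs_years, observed = obs[[v]],
                 predicted_factual = truth[[v]],
                 predicted_counterfactual =
                   site_series(pair$counterfactual, obs_years, v),
                 disturbance_year = dist_year, disturbance_type = types[s])
    }))
  }
  out <- do.call(rbind, rec)
  rownames(out) <- NULL
  out
}

#' Assemble a chronosequence from site records
#'
#' Summarises each site x variable to a single equal-weight row positioned
#' at its years since disturbance (observation years minus the disturbance
#' year; the most recent event anchors multi-event sites). Sites without a
#' resolvable disturbance year are excluded with a warning. Record length
#' does not weight any aggregate built from the output: one site, one row.
#'
#' @param records Long data frame as returned by [simulate_site_network()]
#'   (columns `site_id`, `variable`, `year`, `observed`,
#'   `predicted_factual`, `predicted_counterfactual`, `disturbance_year`).
#' @return Data frame with one row per site x variable: `years_since`
#'   (mean over the record), `years_since_min`, `years_since_max`,
#'   `mae_factual`, `mae_counterfactual`, `delta_mae`, `n_obs`.
#' @export
build_chronosequence <- function(records) {
  bad <- is.na(records$disturbance_year)
  if (any(bad)) {
    warning("excluding ", length(unique(records$site_id[bad])),
            " site(s) without a resolvable disturbance year")
    records <- records[!bad, , drop = FALSE]
  }
  if (anyNA(match(records$year, records$year))) stop("records malformed")
  key <- interaction(records$site_id, records$variable, drop = TRUE)
  pieces <- lapply(split(records, key), function(d) {
    dy <- d$disturbance_year[1]
    if (length(unique(d$disturbance_year)) > 1) dy <- max(d$disturbance_year)
    ys <- d$year - dy
    data.frame(site_id = d$site_id[1], variable = d$variable[1],
               years_since = mean(ys), years_since_min = min(ys),
               years_since_max = max(ys),
               mae_factual = mae(d$predicted_factual, d$observed),
               mae_counterfactual = mae(d$predicted_counterfactual,
                                        d$observed),
               delta_mae = delta_mae(d$predicted_factual,
                                     d$predicted_counterfactual, d$observed),
               n_obs = nrow(d))
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$variable, out$years_since), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bin a chronosequence by years since disturbance
#'
#' Simple equal-weight binning of the per-site summaries (default 5-yr
#' bins), the package's aggregation for recovery-curve summaries.
#'
#' @param chrono Output of [build_chronosequence()].
#' @param width Bin width in years.
#' @return Data frame: `variable`, `bin_start`, mean `delta_mae`, `n_sites`.
#' @export
chrono_bins <- function(chrono, width = 5) {
  b <- floor(chrono$years_since / width) * width
  key <- interaction(chrono$variable, b, drop = TRUE)
  out <- do.call(rbind, lapply(split(chrono, key), function(d) {
    data.frame(variable = d$variable[1],
               bin_start = floor(d$years_since[1] / width) * width,
               delta_mae = mean(d$delta_mae), n_sites = nrow(d))
  }))
  out <- out[order(out$variable, out$bin_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
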