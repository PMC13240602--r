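#' Convert a carbon mass to CO2-equivalent mass
#'
#' Multiplies by the molar mass ratio 44/12, e.g. 210 Tg C becomes 770 Tg
#' CO2.
#'
#' @param c_mass Carbon mass (any unit).
#' @param ratio Molar mass ratio, default 44/12.
#' @return CO2 mass in the same unit.
#' @export
c_to_co2 <- function(c_mass, ratio = 44 / 12) c_mass * ratio

#' National pool-and-flux balance sheet
#'
#' Area-weights a run's per-cell pools and fluxes into domain totals: pool
#' masses in Pg C, fluxes in Tg C yr^-1 with CO2 equivalents (x 44/12),
#' averaged over a window. The default method turns a per-cell flux vector
#' (kg C m^-2 yr^-1) and cell areas (m^2) into a Tg C yr^-1 total.
#'
#' @param x A `carbon_sim` object, or a numeric per-cell flux vector.
#' @param ... Method arguments.
#' @return For `carbon_sim`: object of class `national_summary` (pool
#'   totals in Pg C, flux totals in Tg C yr^-1 and Tg CO2 yr^-1). Default
#'   method: a Tg C yr^-1 scalar.
#' @export
national_summary <- function(x, ...) UseMethod("national_summary")

#' @rdname national_summary
#' @param area Cell areas, m^2 (recycled).
#' @param co2_mass_ratio Molar mass ratio for CO2 equivalents.
#' @export
national_summary.default <- function(x, area, co2_mass_ratio = 44 / 12, ...) {
  if (any(area <= 0)) stop("cell areas must be positive")
  sum(x * area) * 1e-9  # kg -> Tg
}

#' @rdname national_summary
#' @param window `c(start, end)` averaging window, years; default the full
#'   run.
#' @export
national_summary.carbon_sim <- function(x, window = NULL,
                                        co2_mass_ratio = 44 / 12, ...) {
  if (is.null(window)) window <- range(x$years)
  sel <- x$years >= window[1] & x$years <= window[2]
  if (!any(sel)) stop("window outside the simulated years")
  area <- rep(x$cell_area, length(x$cells))

  pools_mean <- apply(x$pool_state[, sel, , drop = FALSE], c(1, 3), mean)
  pools_pg <- as.numeric(pools_mean %*% area) * 1e-12  # kg -> Pg
  names(pools_pg) <- POOL_NAMES

  fl <- sapply(x$fluxes, function(m) sum(colMeans(m[sel, , drop = FALSE]) *
                                           area) * 1e-9)
  structure(list(window = window, pools_pg = pools_pg,
                 fluxes_tg = fl, fluxes_tg_co2 = fl * co2_mass_ratio,
                 area_total = sum(area)),
            class = "national_summary")
}

#' @export
print.national_summary <- function(x, ...) {
  cat(sprintf("domain balance sheet, %d-%d (area %.3g m^2)\n",
              x$window[1], x$window[2], x$area_total))
  cat("pools (Pg C):\n")
  for (nm in names(x$pools_pg))
    cat(sprintf("  %-15s %8.3f\n", nm, x$pools_pg[[nm]]))
  cat(sprintf("  %-15s %8.3f\n", "TOTAL", sum(x$pools_pg)))
  cat("fluxes (Tg C yr^-1 | Tg CO2 yr^-1):\n")
  for (nm in c("gpp", "ra", "rh", "nep", "fire_co2", "product_emission",
               "nbp"))
    cat(sprintf("  %-17s %9.2f | %9.2f\n", nm, x$fluxes_tg[[nm]],
                x$fluxes_tg_co2[[nm]]))
  invisible(x)
}

ols_slope <- function(x, y) {
  n <- length(x)
  xc <- x - mean(x); yc <- y - mean(y)
  sxx <- sum(xc^2)
  slope <- sum(xc * yc) / sxx
  res <- yc - slope * xc
  s2 <- sum(res^2) / (n - 2)
  se <- sqrt(s2 / sxx)
  if (!is.finite(se) || se == 0) {
    p <- if (slope == 0) 1 else 0
  } else {
    p <- 2 * stats::pt(-abs(slope / se), df = n - 2)
  }
  c(slope = slope, se = se, p = p)
}

#' Rolling-window trend tests on an annual series
#'
#' Ordinary least-squares slope in every sliding window (default 15 years)
#' with a two-sided t-test on the slope. A window is flagged
#' (`flag_sign_change`) when its slope is significantly negative and the
#' running mean of the series (default 10-year) changes sign across the
#' window -- the configuration in which a declining trend would flip the
#' smoothed series from sink to source. Constant windows get slope 0 and
#' p = 1. No multiple-testing correction is applied across windows; the
#' p-values are raw per-window values.
#'
#' @param series Annual numeric series.
#' @param years Calendar years (default consecutive from 1).
#' @param window Window length, years (default 15).
#' @param alpha Significance level for the negative-trend flag.
#' @param smooth_window Running-mean length for the sign-change flag.
#' @return Data frame with one row per window: `start`, `end`, `slope`,
#'   `se`, `p_value`, `significant_negative`, `flag_sign_change`.
#' @export
rolling_trend <- function(series, years = seq_along(series), window = 15,
                          alpha = 0.05, smooth_window = 10) {
  n <- length(series)
  if (n < window) stop("series shorter than the trend window")
  rm_ <- running_mean(series, smooth_window, years)
  nw <- n - window + 1
  out <- data.frame(start = years[seq_len(nw)],
                    end = years[seq_len(nw) + window - 1],
                    slope = NA_real_, se = NA_real_, p_value = NA_real_)
  for (i in seq_len(nw)) {
    idx <- i:(i + window - 1)
    fit <- ols_slope(years[idx], series[idx])
    out$slope[i] <- fit[["slope"]]
    out$se[i] <- fit[["se"]]
    out$p_value[i] <- fit[["p"]]
  }
  out$significant_negative <- out$slope < 0 & out$p_value < alpha
  flag <- logical(nw)
  for (i in seq_len(nw)) {
    idx <- i:(i + window - 1)
    rmw <- rm_$value[rm_$end %in% years[idx]]
    flag[i] <- out$significant_negative[i] && length(rmw) > 1 &&
      any(sign(rmw[-1]) != sign(rmw[1]) & rmw[-1] != 0)
  }
  out$flag_sign_change <- flag
  out
}

# Trailing running mean; each value is placed both at its window end year
# and at the mean year of its window (fractional time axis), the latter so
# that a linear series keeps its zero crossing unmoved.
running_mean <- function(series, window, years = seq_along(series)) {
  n <- length(series)
  if (n < window) stop("series shorter than the smoothing window")
  cs <- cumsum(series)
  v <- (cs[window:n] - c(0, cs)[seq_len(n - window + 1)]) / window
  end <- years[window:n]
  data.frame(end = end, time = end - (window - 1) / 2, value = v)
}

#' Estimate the source-sink transition year of an NBP ensemble
#'
#' For each ensemble member, smooths the annual series with a running mean
#' (default 10-year; values are placed at the mean year of their window, so
#' a linear series keeps its zero crossing exactly), fits an OLS line to
#' the last `trend_window` smoothed values, and extrapolates that line to
#' its zero crossing -- the year the smoothed series crosses from sink
#' (positive) to source (negative). Members whose fitted trend is not
#' negative are reported as non-crossing, never dropped; the ensemble mean
#' and standard deviation are computed over the crossing members.
#'
#' @param ensemble Numeric matrix (years x members), or a list of equal
#'   length numeric series, or a single series.
#' @param years Calendar years of the series rows.
#' @param trend_window Years of smoothed series in the trend fit
#'   (default 15).
#' @param smooth_window Running-mean length (default 10).
#' @return Object of class `crossing_year_est`: per-member crossing years
#'   (`NA` for non-crossing members), `mean`, `sd`, `n_crossing`,
#'   `n_no_crossing`.
#' @export
crossing_year <- function(ensemble, years, trend_window = 15,
                          smooth_window = 10) {
  if (is.list(ensemble)) ensemble <- do.call(cbind, ensemble)
  if (is.null(dim(ensemble))) ensemble <- matrix(ensemble, ncol = 1)
  if (nrow(ensemble) != length(years))
    stop("years must match the ensemble rows")
  if (nrow(ensemble) < smooth_window + trend_window - 1)
    stop("series too short for the smoothing and trend windows")
  cross <- rep(NA_real_, ncol(ensemble))
  for (m in seq_len(ncol(ensemble))) {
    rm_ <- running_mean(ensemble[, m], smooth_window, years)
    k <- nrow(rm_)
    idx <- (k - trend_window + 1):k
    fit <- ols_slope(rm_$time[idx], rm_$value[idx])
    b <- fit[["slope"]]
    a <- mean(rm_$value[idx]) - b * mean(rm_$time[idx])
    if (b < 0) cross[m] <- -a / b
  }
  ok <- !is.na(cross)
  structure(list(crossing = cross,
                 mean = if (any(ok)) mean(cross[ok]) else NA_real_,
                 sd = if (sum(ok) > 1) stats::sd(cross[ok]) else NA_real_,
                 n_crossing = sum(ok), n_no_crossing = sum(!ok)),
            class = "crossing_year_est")
}

#' @export
print.crossing_year_est <- function(x, ...) {
  if (x$n_crossing == 0) {
    cat("source-sink transition: no ensemble member crosses zero\n")
  } else {
    cat(sprintf("source-sink transition: %.1f (sd %s, %d/%d members cross)\n",
                x$mean, if (is.na(x$sd)) "NA" else sprintf("%.2f", x$sd),
                x$n_crossing, x$n_crossing + x$n_no_crossing))
  }
  invisible(x)
}
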