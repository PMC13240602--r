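#' Construct and validate a forcing table
#'
#' A forcing object is a long data frame with one row per cell-year carrying
#' the annual drivers of a simulation: air-temperature anomaly (deg C),
#' a precipitation index (unitless, carried for completeness), atmospheric
#' CO2 (ppm, common across cells within a year), and the annual burned and
#' harvested area fractions of each cell. A 12-element monthly burn
#' climatology (used only to disaggregate annual burned area for monthly
#' reporting) and a nominal per-cell area (m^2) are attached as attributes.
#'
#' @param df Data frame with columns `year`, `cell`, `tair_anomaly`,
#'   `precip_index`, `co2_ppm`, `burned_frac`, `harvest_frac`.
#' @param monthly_weights 12 non-negative weights summing to 1; default is a
#'   boreal fire-season climatology peaking in July.
#' @param cell_area Nominal area represented by each cell, m^2. The default
#'   divides a 4e12 m^2 (400 Mha) burnable domain evenly across the cells.
#' @return `df` with class `carbon_forcing` and the attributes attached.
#' @export
carbon_forcing <- function(df,
                           monthly_weights = default_burn_climatology(),
                           cell_area = NULL) {
  req <- c("year", "cell", "tair_anomaly", "precip_index", "co2_ppm",
           "burned_frac", "harvest_frac")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("forcing is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  num_cols <- setdiff(req, "cell")
  for (cl in num_cols) {
    if (!is.numeric(df[[cl]])) stop("forcing column ", cl, " must be numeric")
    if (anyNA(df[[cl]]) || any(!is.finite(df[[cl]])))
      stop("forcing column ", cl, " contains NA or non-finite values")
  }
  if (any(df$co2_ppm <= 0)) stop("co2_ppm must be positive")
  if (any(df$burned_frac < 0 | df$burned_frac > 1))
    stop("burned_frac outside [0, 1]")
  if (any(df$harvest_frac < 0 | df$harvest_frac > 1))
    stop("harvest_frac outside [0, 1]")
  if (any(df$burned_frac + df$harvest_frac > 1 + 1e-12))
    stop("burned_frac + harvest_frac exceeds 1 for some cell-years")
  if (length(monthly_weights) != 12L || any(monthly_weights < 0))
    stop("monthly_weights must be 12 non-negative values")
  if (abs(sum(monthly_weights) - 1) > 1e-12)
    stop("monthly_weights must sum to 1")
  df <- df[order(df$cell, df$year), , drop = FALSE]
  rownames(df) <- NULL
  if (is.null(cell_area))
    cell_area <- 4e12 / length(unique(df$cell))
  attr(df, "monthly_weights") <- monthly_weights
  attr(df, "cell_area") <- cell_area
  class(df) <- c("carbon_forcing", "data.frame")
  df
}

#' Default monthly burned-area climatology
#'
#' Twelve weights summing to 1 describing the within-year distribution of
#' burned area in a boreal fire regime (May-September fire season peaking in
#' July). Used only to disaggregate annual burned area for monthly
#' reporting; pools are stepped annually.
#'
#' @return Numeric vector of length 12.
#' @export
default_burn_climatology <- function() {
  w <- c(0, 0, 0.01, 0.03, 0.10, 0.20, 0.30, 0.22, 0.10, 0.03, 0.01, 0)
  w / sum(w)
}

#' @export
print.carbon_forcing <- function(x, ...) {
  yrs <- range(x$year)
  cat(sprintf("forcing: %d cells x years %d-%d (%d cell-years)\n",
              length(unique(x$cell)), yrs[1], yrs[2], nrow(x)))
  cat(sprintf("  CO2 %.1f-%.1f ppm | mean burned %.4f | mean harvest %.4f\n",
              min(x$co2_ppm), max(x$co2_ppm),
              mean(x$burned_frac), mean(x$harvest_frac)))
  cat(sprintf("  cell area %.3g m^2\n", attr(x, "cell_area")))
  invisible(x)
}
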