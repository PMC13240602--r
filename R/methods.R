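#' @export
print.carbon_sim <- function(x, ...) {
  led <- flux_ledger(x, "mean")
  cat(sprintf("carbon_sim: %d cell(s), %d-%d (%s protocol)\n",
              length(x$cells), min(x$years), max(x$years), x$protocol$type))
  cat(sprintf("  drivers: climate %s, CO2 %s, disturbance %s%s\n",
              x$drivers$climate, x$drivers$co2, x$drivers$disturbance,
              if (is.null(x$drivers$disturbance_from)) "" else
                paste0(" (from ", x$drivers$disturbance_from, ")")))
  cat(sprintf("  mean NBP %.4f kg C m-2 yr-1 | mean GPP %.3f | final AGB %.2f\n",
              mean(led$nbp), mean(led$gpp),
              mean(x$agb[nrow(x$agb), ])))
  cat(sprintf("  max carbon-closure residual %.2e (relative)\n",
              x$max_closure_residual))
  invisible(x)
}

#' Summarise a simulation by era
#'
#' @param object A `carbon_sim` object.
#' @param eras Breaks (years) splitting the run into reporting eras.
#' @param ... Unused.
#' @return Data frame of era-mean fluxes (kg C m^-2 yr^-1), printed with
#'   closure diagnostics.
#' @export
summary.carbon_sim <- function(object, eras = NULL, ...) {
  led <- flux_ledger(object, "mean")
  if (is.null(eras)) {
    rng <- range(object$years)
    eras <- unique(round(seq(rng[1], rng[2] + 1, length.out = 4)))
  }
  bin <- cut(led$year, breaks = eras, right = FALSE, dig.lab = 6)
  keep <- !is.na(bin)
  agg <- stats::aggregate(led[keep, c("gpp", "er", "nep", "fire_co2",
                                      "product_emission", "nbp")],
                          list(era = bin[keep]), mean)
  out <- structure(list(table = agg,
                        closure = object$max_closure_residual,
                        years = range(object$years)),
                   class = "summary.carbon_sim")
  out
}

#' @export
print.summary.carbon_sim <- function(x, ...) {
  cat(sprintf("era-mean fluxes (kg C m-2 yr-1), %d-%d:\n",
              x$years[1], x$years[2]))
  print(x$table, row.names = FALSE, digits = 4)
  cat(sprintf("max annual carbon-closure residual: %.2e relative\n",
              x$closure))
  invisible(x)
}

#' Plot the NBP trajectory of a run
#'
#' Annual domain-mean NBP with its 10-year running mean and a zero line
#' (positive = land sink).
#'
#' @param x A `carbon_sim` object.
#' @param smooth_window Running-mean window, years.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.carbon_sim <- function(x, smooth_window = 10, ...) {
  led <- flux_ledger(x, "mean")
  graphics::plot(led$year, led$nbp, type = "l", col = "grey60",
                 xlab = "year", ylab = "NBP (kg C m-2 yr-1)", ...)
  graphics::abline(h = 0, lty = 3)
  if (nrow(led) >= smooth_window) {
    rm_ <- running_mean(led$nbp, smooth_window, led$year)
    graphics::lines(rm_$time, rm_$value, lwd = 2)
  }
  invisible(x)
}

#' @export
coef.carbon_sim <- function(object, ...) {
  p <- object$params
  c(gpp_max = p$gpp_max, vcmax_scale = p$vcmax_scale,
    respiration_scale = p$respiration_scale, gamma = p$gamma, c0 = p$c0,
    tau_rec = p$tau_rec, beta_gpp = p$beta_gpp, q10 = p$q10)
}
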