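#' Plant-functional-type parameters
#'
#' Bundles the physiological and turnover parameters of one plant functional
#' type (PFT). Defaults describe a needleleaf boreal conifer stand and embed
#' three headline calibration scalings: the maximum carboxylation capacity is
#' raised by 11% (`vcmax_scale = 1.11`), all basal/maintenance/growth
#' respiration rates are reduced by 25% (`respiration_scale = 0.75`), and the
#' CO2-fertilization downregulation parameter is `gamma = 0.5` (unitless),
#' which halves the unmodified logarithmic GPP response to rising CO2.
#'
#' Annual gross primary productivity of a tile is
#' \deqn{GPP = gpp_{max} \cdot vcmax\_scale \cdot (1 - e^{-age/\tau_{rec}})
#'       \cdot e^{\beta_{gpp} \Delta T} \cdot (1 + \gamma \ln(c/c_0))}
#' Maintenance respiration is proportional to live pool mass with a Q10
#' temperature response; growth respiration is a fixed fraction of the
#' post-maintenance assimilate.
#'
#' @param woody Logical; woody PFT.
#' @param leaf_habit One of "needleleaf", "broadleaf", "nonwoody". Controls
#'   which stem combustion fractions apply during fire.
#' @param gpp_max Unstressed mature-stand GPP, kg C m^-2 yr^-1 (before the
#'   vcmax scaling).
#' @param tau_rec Recovery timescale of the age response, yr. The default 18 yr
#'   puts the GPP plateau roughly 50 yr after stand-replacing disturbance.
#' @param beta_gpp GPP climate sensitivity, per deg C of temperature anomaly.
#' @param q10 Q10 of maintenance and heterotrophic respiration.
#' @param alloc Named allocation fractions of NPP to `leaf`, `stem`, `root`;
#'   must sum to 1.
#' @param tau_leaf Green-leaf residence time before transfer to brown leaf, yr.
#' @param tau_brown Brown-leaf residence time before transfer to litter, yr.
#' @param tau_stem,tau_root Stem and root turnover times to litter, yr.
#' @param rm_rates Named basal maintenance respiration rates (fraction of pool
#'   per yr) for `green_leaf`, `brown_leaf`, `stem`, `root`.
#' @param rg_frac Growth respiration as a fraction of (GPP - maintenance).
#' @param k_litter,k_soil Base decomposition rates of litter and soil, yr^-1.
#' @param humification Fraction of the litter decomposition flux transferred
#'   to soil (the remainder is respired as Rh).
#' @param respiration_scale Multiplier on all respiration rates (default 0.75).
#' @param vcmax_scale Multiplier on GPP representing the raised carboxylation
#'   capacity (default 1.11).
#' @param gamma CO2 downregulation parameter in `[0, 1]` (default 0.5).
#' @param c0 Reference CO2 concentration, ppm. Normally set by the run
#'   protocol to the spin-up year concentration; the default 289 ppm is the
#'   low end of the 1900-2023 historical range.
#' @return Object of class `pft_params`.
#' @seealso [co2_response()], [step_year()], [carbon_sim()]
#' @export
pft_params <- function(woody = TRUE,
                       leaf_habit = c("needleleaf", "broadleaf", "nonwoody"),
                       gpp_max = 0.9,
                       tau_rec = 18,
                       beta_gpp = 0.02,
                       q10 = 2.0,
                       alloc = c(leaf = 0.30, stem = 0.45, root = 0.25),
                       tau_leaf = 4,
                       tau_brown = 1,
                       tau_stem = 20,
                       tau_root = 12,
                       rm_rates = c(green_leaf = 0.20, brown_leaf = 0,
                                    stem = 0.010, root = 0.10),
                       rg_frac = 0.25,
                       k_litter = 0.15,
                       k_soil = 0.02,
                       humification = 0.30,
                       respiration_scale = 0.75,
                       vcmax_scale = 1.11,
                       gamma = 0.5,
                       c0 = 289) {
  leaf_habit <- match.arg(leaf_habit)
  p <- list(woody = woody, leaf_habit = leaf_habit, gpp_max = gpp_max,
            tau_rec = tau_rec, beta_gpp = beta_gpp, q10 = q10,
            alloc = alloc, tau_leaf = tau_leaf, tau_brown = tau_brown,
            tau_stem = tau_stem, tau_root = tau_root, rm_rates = rm_rates,
            rg_frac = rg_frac, k_litter = k_litter, k_soil = k_soil,
            humification = humification,
            respiration_scale = respiration_scale,
            vcmax_scale = vcmax_scale, gamma = gamma, c0 = c0)
  validate_pft_params(p)
  class(p) <- "pft_params"
  p
}

validate_pft_params <- function(p) {
  stopifnot(is.logical(p$woody), length(p$woody) == 1L)
  if (abs(sum(p$alloc) - 1) > 1e-12)
    stop("allocation fractions must sum to 1 (got ", sum(p$alloc), ")")
  if (!all(c("leaf", "stem", "root") %in% names(p$alloc)))
    stop("alloc must name leaf, stem, root")
  rates <- c(p$gpp_max, p$tau_rec, p$q10, p$tau_leaf, p$tau_brown,
             p$tau_stem, p$tau_root, p$k_litter, p$k_soil)
  if (any(rates <= 0)) stop("all timescales and rates must be > 0")
  if (p$gamma < 0 || p$gamma > 1) stop("gamma must lie in [0, 1]")
  if (p$c0 <= 0) stop("reference CO2 c0 must be positive")
  if (p$humification < 0 || p$humification >= 1)
    stop("humification fraction must lie in [0, 1)")
  if (any(p$rm_rates < 0)) stop("maintenance respiration rates must be >= 0")
  invisible(p)
}

#' @export
print.pft_params <- function(x, ...) {
  cat("PFT parameters (", x$leaf_habit, if (x$woody) ", woody" else "",
      ")\n", sep = "")
  cat(sprintf("  gpp_max %.3f kg C m-2 yr-1 x vcmax_scale %.2f | tau_rec %g yr\n",
              x$gpp_max, x$vcmax_scale, x$tau_rec))
  cat(sprintf("  gamma %.2f (CO2 downregulation, c0 = %g ppm)\n", x$gamma, x$c0))
  cat(sprintf("  respiration_scale %.2f | q10 %.1f | beta_gpp %.3f per degC\n",
              x$respiration_scale, x$q10, x$beta_gpp))
  cat("  alloc:", paste(sprintf("%s %.2f", names(x$alloc), x$alloc),
                        collapse = ", "), "\n")
  invisible(x)
}

#' Fire carbon-partitioning table
#'
#' Per-tissue fractions of a burned tile's carbon released as CO2 and
#' converted to litter during stand-replacing wildfire. Defaults are the
#' calibrated combustion partitioning for boreal stands: green leaf
#' (woody 0.67 to CO2 / 0.32 to litter; nonwoody 0.82 / 0.17), brown leaf
#' (0.90 / 0.09, PFT-invariant), stem (needleleaf trees and shrubs
#' 0.165 / 0.83; broadleaf 0.125 / 0.87). The small residual of each live
#' tissue (e.g. 0.01 of green leaf) is retained as live carbon on the new
#' age-0 tile, implicitly representing standing dead and surviving
#' structure. Roots are assumed not to combust (all killed root mass goes to
#' litter), and fractions 0.10 of litter and 0.02 of soil carbon combust;
#' these three are calibration knobs, not literature constants.
#'
#' @param green_leaf_woody,green_leaf_nonwoody,brown_leaf,stem_needleleaf,stem_broadleaf
#'   Length-2 numeric `c(to_co2, to_litter)` per tissue class.
#' @param root Length-2 `c(to_co2, to_litter)` for killed roots.
#' @param litter_combust,soil_combust Fractions of litter and soil carbon
#'   released as CO2 by the fire.
#' @return Object of class `fire_partition_table`.
#' @export
fire_partition_table <- function(green_leaf_woody = c(0.67, 0.32),
                                 green_leaf_nonwoody = c(0.82, 0.17),
                                 brown_leaf = c(0.90, 0.09),
                                 stem_needleleaf = c(0.165, 0.83),
                                 stem_broadleaf = c(0.125, 0.87),
                                 root = c(0.0, 1.0),
                                 litter_combust = 0.10,
                                 soil_combust = 0.02) {
  tab <- list(green_leaf_woody = green_leaf_woody,
              green_leaf_nonwoody = green_leaf_nonwoody,
              brown_leaf = brown_leaf,
              stem_needleleaf = stem_needleleaf,
              stem_broadleaf = stem_broadleaf,
              root = root,
              litter_combust = litter_combust,
              soil_combust = soil_combust)
  for (nm in setdiff(names(tab), c("litter_combust", "soil_combust"))) {
    fr <- tab[[nm]]
    if (length(fr) != 2L || any(fr < 0) || any(fr > 1))
      stop("fire fractions for ", nm, " must be two values in [0, 1]")
    if (sum(fr) > 1 + 1e-12)
      stop("fire fractions for ", nm, " sum above 1 (", sum(fr), ")")
  }
  if (tab$litter_combust < 0 || tab$litter_combust > 1 ||
      tab$soil_combust < 0 || tab$soil_combust > 1)
    stop("litter/soil combustion fractions must lie in [0, 1]")
  class(tab) <- "fire_partition_table"
  tab
}

#' @export
print.fire_partition_table <- function(x, ...) {
  cat("fire partitioning (fraction to CO2 / to litter; residual stays live):\n")
  f <- function(nm) sprintf("  %-20s %.3f / %.3f\n", nm, x[[nm]][1], x[[nm]][2])
  cat(f("green_leaf_woody"), f("green_leaf_nonwoody"), f("brown_leaf"),
      f("stem_needleleaf"), f("stem_broadleaf"), f("root"), sep = "")
  cat(sprintf("  litter combusted %.2f | soil combusted %.2f\n",
              x$litter_combust, x$soil_combust))
  invisible(x)
}

#' Wood-harvest parameters
#'
#' Fate of carbon during stand-replacing wood harvest: a fraction of stem
#' carbon is removed to harvested-wood product pools (split between a
#' short-lived and a long-lived pool), the stem remainder plus all leaf and
#' root mass becomes logging-residue litter. Product pools decay to the
#' atmosphere at first-order rates reflecting product lifetimes. No printed
#' source values exist for these fractions; the defaults are package choices
#' exposed for configuration.
#'
#' @param stem_to_products Fraction of stem carbon removed to products.
#' @param product_split Length-2 `c(short, long)` split of the removed stem
#'   carbon; must sum to 1.
#' @param decay_rates Length-2 first-order decay rates `c(short, long)`,
#'   yr^-1 (defaults 1/5 and 1/50, i.e. 5- and 50-year lifetimes).
#' @return Object of class `harvest_params`.
#' @export
harvest_params <- function(stem_to_products = 0.85,
                           product_split = c(short = 0.4, long = 0.6),
                           decay_rates = c(short = 1 / 5, long = 1 / 50)) {
  if (stem_to_products < 0 || stem_to_products > 1)
    stop("stem_to_products must lie in [0, 1]")
  if (abs(sum(product_split) - 1) > 1e-12)
    stop("product_split must sum to 1")
  if (any(product_split < 0) || any(product_split > 1))
    stop("product_split fractions must lie in [0, 1]")
  if (any(decay_rates < 0)) stop("product decay rates must be >= 0")
  hp <- list(stem_to_products = stem_to_products,
             product_split = product_split,
             decay_rates = decay_rates)
  class(hp) <- "harvest_params"
  hp
}

#' @export
print.harvest_params <- function(x, ...) {
  cat(sprintf("harvest: %.2f of stem to products (%.2f short / %.2f long),\n",
              x$stem_to_products, x$product_split[1], x$product_split[2]))
  cat(sprintf("  residue + leaves + roots to litter; product decay %.3f / %.3f yr-1\n",
              x$decay_rates[1], x$decay_rates[2]))
  invisible(x)
}

#' Print every default parameter table
#'
#' Provenance helper: prints the default PFT parameters, fire partitioning
#' table and harvest parameters so a run's parameterization can be recorded
#' alongside its outputs.
#'
#' @param params,fire_table,harvest Optional non-default objects to print.
#' @return Invisibly, a list of the three objects.
#' @export
show_params <- function(params = pft_params(),
                        fire_table = fire_partition_table(),
                        harvest = harvest_params()) {
  print(params)
  print(fire_table)
  print(harvest)
  invisible(list(params = params, fire_table = fire_table, harvest = harvest))
}
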