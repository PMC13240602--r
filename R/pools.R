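#' Carbon pool vectors
#'
#' A carbon pool state is a named numeric vector of areal carbon densities
#' (kg C m^-2) over eight compartments: three live above-ground tissues
#' (`green_leaf`, `brown_leaf`, `stem`), live `root`, dead `litter` and `soil`
#' organic matter, and two harvested-wood product pools (`products_short`,
#' `products_long`). Product pools sit inside the state so that harvest is an
#' internal transfer, not an atmospheric flux; carbon only leaves the system
#' through respiration, fire CO2 and product-pool decay.
#'
#' @param green_leaf,brown_leaf,stem,root,litter,soil,products_short,products_long
#'   Non-negative carbon densities, kg C m^-2.
#' @return A named numeric vector of class `carbon_pools`.
#' @examples
#' p <- carbon_pools(stem = 5, litter = 2, soil = 10)
#' total_carbon(p)
#' agb(p)
#' @export
carbon_pools <- function(green_leaf = 0, brown_leaf = 0, stem = 0, root = 0,
                         litter = 0, soil = 0,
                         products_short = 0, products_long = 0) {
  p <- c(green_leaf = green_leaf, brown_leaf = brown_leaf, stem = stem,
         root = root, litter = litter, soil = soil,
         products_short = products_short, products_long = products_long)
  validate_pools(p)
  class(p) <- c("carbon_pools", "numeric")
  p
}

POOL_NAMES <- c("green_leaf", "brown_leaf", "stem", "root",
                "litter", "soil", "products_short", "products_long")

validate_pools <- function(p) {
  if (!is.numeric(p) || length(p) != 8L || !all(POOL_NAMES %in% names(p)))
    stop("carbon pools must be a named numeric vector over the 8 compartments")
  if (anyNA(p)) stop("carbon pools contain NA")
  if (any(p < 0)) {
    bad <- names(p)[p < 0]
    stop("negative carbon pool: ", paste(bad, collapse = ", "))
  }
  invisible(p)
}

#' Total carbon of a pool state
#'
#' Sum over all compartments including wood products, kg C m^-2.
#' @param pools A `carbon_pools` vector (or any named vector over the
#'   same compartments).
#' @return Numeric scalar.
#' @export
total_carbon <- function(pools) sum(pools[POOL_NAMES])

#' Above-ground biomass diagnostic
#'
#' AGB is the live above-ground carbon: green leaf + brown leaf + stem.
#' Roots, dead pools and products are excluded.
#' @inheritParams total_carbon
#' @return Numeric scalar, kg C m^-2.
#' @export
agb <- function(pools) {
  sum(pools[c("green_leaf", "brown_leaf", "stem")])
}

#' @export
print.carbon_pools <- function(x, digits = 4, ...) {
  cat("carbon pools (kg C m^-2):\n")
  print(round(unclass(x), digits))
  cat(sprintf("total %.4f | AGB %.4f\n", total_carbon(x), agb(x)))
  invisible(x)
}
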