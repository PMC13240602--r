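# Shared fixtures: small deterministic forcings and a fast-equilibrating
# parameter set for tests that do not need the default timescales.

flat_forcing <- function(years = 1750:1850, n_cells = 1, seed = 1) {
  gen_forcing(years, n_cells, seed = seed, warming_rate = 0, ar1_sd = 0)
}

fast_params <- function() {
  pft_params(tau_leaf = 1, tau_brown = 1, tau_stem = 1, tau_root = 1,
             k_litter = 0.5, k_soil = 0.5, tau_rec = 3)
}

# random valid tile set with n tiles
random_tiles <- function(n, rng_pools_scale = 5) {
  a <- runif(n)
  a <- a / sum(a)
  pools <- matrix(runif(8 * n) * rng_pools_scale, nrow = 8,
                  dimnames = list(standcycle:::POOL_NAMES, NULL))
  tile_set(a, sample(0:200, n, replace = TRUE), pools)
}
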