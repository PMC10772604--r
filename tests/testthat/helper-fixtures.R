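# Shared fixtures, built in code at test time.

kB_test <- 8.617333262e-5

# hand-built global grid with arbitrary fields; defaults give a 4 x 4 x 2
# toy ocean with hand-set T/pO2 suitable for exact brute-force oracles
toy_grid <- function(nlon = 4, nlat = 4, depth = c(50, 150),
                     T_fun = function(lat, z) 25 - 0.25 * abs(lat) -
                       0.02 * z,
                     pO2_fun = function(lat, z) 0.21 - 0.0009 * z) {
  res <- 360 / nlon
  lat_res <- 180 / nlat
  lon <- seq(-180 + res / 2, 180 - res / 2, by = res)
  lat <- seq(-90 + lat_res / 2, 90 - lat_res / 2, by = lat_res)
  nz <- length(depth)
  Tarr <- array(NA_real_, c(nlon, nlat, nz, 1))
  parr <- array(NA_real_, c(nlon, nlat, nz, 1))
  vol <- array(NA_real_, c(nlon, nlat, nz))
  for (j in seq_len(nlat)) for (k in seq_len(nz)) {
    Tarr[, j, k, 1] <- T_fun(lat[j], depth[k]) + seq_len(nlon) * 0.01
    parr[, j, k, 1] <- pO2_fun(lat[j], depth[k]) + seq_len(nlon) * 1e-4
    # integer multiples of 2^20: all partial sums are exact in doubles,
    # so loop oracles match vectorised sums bit for bit
    vol[, j, k] <- (seq_len(nlon) + 10 * j + 100 * k) * 1048576
  }
  structure(list(lon = lon, lat = lat, depth = depth,
                 month = NA_integer_, T = Tarr, pO2 = parr, volume = vol,
                 mask = array(TRUE, c(nlon, nlat, nz)),
                 resolution_deg = res,
                 depth_bounds = c(0, mean(depth), 2 * depth[2] - mean(depth)),
                 seed = 0, params = NULL),
            class = "env_grid")
}

# a coarse synthetic ocean reused across tests (built once per test run)
test_env <- local({
  env <- NULL
  function() {
    if (is.null(env)) env <<- make_ocean(resolution_deg = 10, seed = 1)
    env
  }
})

# a small fitted-ready occupancy dataset from a known species
test_species_dataset <- function(A = 8, E = 0.3, D = 0.02, seed = 42,
                                 n_presence = 800, noise = 0,
                                 env = test_env(), ...) {
  tr <- trait_set(A, E, D, species_id = "fixture_sp")
  truth <- species_truth(tr, n_presence = n_presence, noise_rate = noise,
                         seed = seed)
  occ <- simulate_species(env, truth)
  list(truth = truth, occurrences = occ,
       dataset = build_occupancy(occ, env, occupancy_opts(...)))
}

# quick manual occupancy object (bypasses gridding) for unit tests
manual_dataset <- function(samples, presence_cells = NULL) {
  if (is.null(presence_cells))
    presence_cells <- samples[samples$label == "presence",
                              c("T", "pO2", "volume")]
  structure(list(species_id = "manual", samples = samples,
                 presence_cells = presence_cells,
                 n_presence_cells = nrow(presence_cells),
                 counts = list(), universe = "cells",
                 skipped = FALSE, skip_reason = NA_character_),
            class = "occupancy")
}
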