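#' Parameters of the synthetic ocean climatology
#'
#' Defaults emulate the large-scale structure of observed climatologies: a
#' warm tropical surface cooling poleward and with depth, cold-water surface
#' O2 supersaturation, and a low-latitude mid-depth oxygen-minimum zone that
#' recovers toward the abyss.
#'
#' @param T_tropical Maximum surface temperature at the equator, degC.
#' @param T_polar Minimum (polar) surface temperature, degC.
#' @param T_deep Deep-ocean asymptotic temperature, degC.
#' @param z_thermocline e-folding depth of the thermal stratification, m.
#' @param p_surface Surface pO2 in warm water, atm.
#' @param supersat_cold Fractional surface supersaturation reached in the
#'   coldest water (cold water holds more O2 at equilibrium).
#' @param p_surface_max Hard upper bound on pO2 anywhere, atm.
#' @param p_deep_pole,p_deep_eq Deep-water pO2 at the poles (young,
#'   ventilated water) and at the equator (old water depleted by
#'   respiration), atm. Deep pO2 recovers from the OMZ minimum but only
#'   partially, as in observed climatologies.
#' @param z_o2 e-folding depth (m) of the transition from surface-saturated
#'   to deep pO2.
#' @param p_omz_min Minimum pO2 in the core of the low-latitude oxygen
#'   minimum zone, atm.
#' @param z_omz,omz_width Depth (m) of the OMZ core and its Gaussian width.
#' @param omz_lat_width Latitudinal e-folding half-width (deg) of the OMZ.
#' @param lon_anomaly_sd Standard deviation (degC) of a smooth, seeded
#'   longitudinal temperature anomaly; 0 (default) gives a zonally symmetric
#'   (zonal-mean) climatology.
#' @param land_fraction Fraction of (lon, lat) columns masked as land,
#'   chosen at random from the seed; 0 (default) is an all-ocean world.
#' @param seasonal_amp Surface amplitude (degC) of the sinusoidal seasonal
#'   cycle used when a monthly grid is requested.
#' @return A list of parameters for [make_ocean()].
#' @export
ocean_params <- function(T_tropical = 29, T_polar = -1.8, T_deep = 2,
                         z_thermocline = 300,
                         p_surface = 0.21, supersat_cold = 0.05,
                         p_surface_max = 0.23,
                         p_deep_pole = 0.16, p_deep_eq = 0.06, z_o2 = 250,
                         p_omz_min = 0.02, z_omz = 350, omz_width = 300,
                         omz_lat_width = 30,
                         lon_anomaly_sd = 0, land_fraction = 0,
                         seasonal_amp = 4) {
  as.list(environment())
}

#' Generate a synthetic gridded ocean climatology
#'
#' Builds an `env_grid` of temperature (degC), O2 partial pressure (atm) and
#' cell volume (m^3) on a regular lat/lon grid with standard depth levels.
#' The construction is deterministic given `seed` (randomness enters only
#' through the optional longitude anomaly and land mask).
#'
#' @param resolution_deg Grid resolution in degrees; must divide 180.
#' @param depth_levels Depth-level centres, m, positive ascending.
#' @param params See [ocean_params()].
#' @param seed Integer seed for the optional stochastic components.
#' @param monthly If `TRUE`, produce 12 monthly temperature fields with a
#'   hemisphere-phased sinusoidal seasonal cycle decaying with depth; pO2 is
#'   held at its annual value.
#' @return An object of class `"env_grid"`: list with axes `lon`, `lat`,
#'   `depth`, `month`, arrays `T` and `pO2` of dim (lon, lat, depth, month),
#'   `volume` and logical `mask` of dim (lon, lat, depth), plus metadata.
#' @examples
#' env <- make_ocean(resolution_deg = 10)
#' sum(env$volume)  # total ocean volume, m^3
#' @export
make_ocean <- function(resolution_deg = 2,
                       depth_levels = c(10, 30, 50, 75, 100, 150, 200,
                                        300, 400, 500, 700, 1000),
                       params = ocean_params(), seed = 1,
                       monthly = FALSE) {
  if (resolution_deg <= 0 || (180 %% resolution_deg) != 0)
    stop("resolution_deg must be positive and divide 180")
  if (any(depth_levels <= 0) || is.unsorted(depth_levels, strictly = TRUE))
    stop("depth_levels must be positive and strictly ascending")
  p <- params
  res <- resolution_deg
  lat <- seq(-90 + res / 2, 90 - res / 2, by = res)
  lon <- seq(-180 + res / 2, 180 - res / 2, by = res)
  z <- depth_levels
  nlat <- length(lat); nlon <- length(lon); nz <- length(z)
  month <- if (monthly) 1:12 else NA_integer_
  nmon <- length(month)

  # layer interfaces: surface, midpoints, bottom extended by half the last gap
  z_bounds <- c(0, (z[-nz] + z[-1]) / 2,
                z[nz] + (z[nz] - if (nz > 1) (z[nz - 1] + z[nz]) / 2 else 0))
  thickness <- diff(z_bounds)

  latr <- lat * pi / 180
  # zonal-mean surface temperature: tropical maximum, polar minimum
  T_surf <- p$T_polar + (p$T_tropical - p$T_polar) * cos(latr)^3
  # vertical structure: exponential decay toward the deep value
  Tmat <- outer(T_surf - p$T_deep, exp(-z / p$z_thermocline)) + p$T_deep

  # surface pO2: supersaturated in cold water
  coldness <- (p$T_tropical - T_surf) / (p$T_tropical - p$T_polar)
  p_surf <- p$p_surface * (1 + p$supersat_cold * coldness)
  # deep water: ventilated (high pO2) at the poles, respired (low) in the
  # tropics; vertical transition from the saturated surface layer
  p_deep <- p$p_deep_eq + (p$p_deep_pole - p$p_deep_eq) * sin(latr)^2
  w_s <- exp(-z / p$z_o2)
  base <- outer(p_surf, w_s) + outer(p_deep, 1 - w_s)  # (lat, depth)
  # OMZ: Gaussian dip in depth, centred at low latitudes, recovering (only
  # partially) toward the deep value below the core
  omz_lat <- exp(-(lat / p$omz_lat_width)^2)
  dip <- outer(omz_lat, exp(-((z - p$z_omz) / p$omz_width)^2))
  pO2mat <- base * (1 - dip) + p$p_omz_min * dip       # (lat, depth)
  pO2mat <- pmin(pmax(pO2mat, 0), p$p_surface_max)

  # expand zonally; optional smooth seeded longitude anomaly on T
  Tarr <- aperm(array(Tmat, dim = c(nlat, nz, nlon)), c(3, 1, 2))
  pO2arr <- aperm(array(pO2mat, dim = c(nlat, nz, nlon)), c(3, 1, 2))
  mask <- array(TRUE, dim = c(nlon, nlat, nz))

  draws <- .with_seed(seed, {
    lonr <- lon * pi / 180
    ph <- stats::runif(2, 0, 2 * pi)
    amp <- stats::rnorm(2, 0, max(p$lon_anomaly_sd, .Machine$double.eps))
    anom <- amp[1] * sin(lonr + ph[1]) + amp[2] * sin(2 * lonr + ph[2])
    land_cols <- if (p$land_fraction > 0)
      sample.int(nlon * nlat, round(p$land_fraction * nlon * nlat))
    else integer(0)
    list(anom = anom, land_cols = land_cols)
  })
  if (p$lon_anomaly_sd > 0) {
    decay <- exp(-z / p$z_thermocline)
    for (k in seq_len(nz))
      Tarr[, , k] <- Tarr[, , k] + outer(draws$anom * decay[k], rep(1, nlat))
    Tarr <- pmax(Tarr, -2)
  }
  for (ic in draws$land_cols) {
    i <- ((ic - 1) %% nlon) + 1
    j <- ((ic - 1) %/% nlon) + 1
    mask[i, j, ] <- FALSE
  }

  # spherical-shell cell volumes: R^2 * dlon * (sin(top) - sin(bottom)) * dz
  R <- 6371000
  lat_edges <- seq(-90, 90, by = res) * pi / 180
  band_area <- R^2 * (res * pi / 180) * diff(sin(lat_edges))  # per lon cell
  vol <- array(0, dim = c(nlon, nlat, nz))
  for (k in seq_len(nz))
    vol[, , k] <- outer(rep(1, nlon), band_area) * thickness[k]
  vol[!mask] <- 0

  Tfull <- array(NA_real_, dim = c(nlon, nlat, nz, nmon))
  pO2full <- array(NA_real_, dim = c(nlon, nlat, nz, nmon))
  if (monthly) {
    decay <- exp(-z / p$z_thermocline)
    for (m in 1:12) {
      # southern-hemisphere summer peaks in February, northern in August
      phase <- cos(2 * pi * (m - 2) / 12)
      seas <- p$seasonal_amp * sin(abs(latr)) * phase * sign(-lat)
      for (k in seq_len(nz)) {
        Tfull[, , k, m] <- Tarr[, , k] +
          outer(rep(1, nlon), seas * decay[k])
        pO2full[, , k, m] <- pO2arr[, , k]
      }
    }
    Tfull <- pmax(Tfull, -2)
  } else {
    Tfull[, , , 1] <- Tarr
    pO2full[, , , 1] <- pO2arr
  }

  structure(
    list(lon = lon, lat = lat, depth = z, month = month,
         T = Tfull, pO2 = pO2full, volume = vol, mask = mask,
         resolution_deg = res, depth_bounds = z_bounds, seed = seed,
         params = p),
    class = "env_grid"
  )
}

#' @export
print.env_grid <- function(x, ...) {
  cat(sprintf("Synthetic ocean grid: %g deg, %d x %d x %d cells%s\n",
              x$resolution_deg, length(x$lon), length(x$lat),
              length(x$depth),
              if (length(x$month) > 1) " x 12 months" else " (annual)"))
  cat(sprintf("  T    in [%.2f, %.2f] degC\n", min(x$T), max(x$T)))
  cat(sprintf("  pO2  in [%.4f, %.4f] atm\n", min(x$pO2), max(x$pO2)))
  cat(sprintf("  ocean volume %.3e m^3 (%d land columns)\n",
              sum(x$volume), sum(!x$mask[, , 1])))
  invisible(x)
}

# annual-mean (lon, lat, depth) fields; identity for annual grids
annual_mean_fields <- function(env) {
  nm <- dim(env$T)[4]
  if (nm == 1L) {
    list(T = env$T[, , , 1, drop = TRUE], pO2 = env$pO2[, , , 1, drop = TRUE])
  } else {
    list(T = apply(env$T, 1:3, mean), pO2 = apply(env$pO2, 1:3, mean))
  }
}

# run expr with a private RNG stream, restoring the caller's state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Convert dissolved O2 concentration to partial pressure
#'
#' Henry's-law conversion using the Garcia & Gordon (1992) refit of the
#' Benson & Krause O2 solubility data: `pO2 = 0.20946 atm * conc / conc_sat`,
#' where `conc_sat(T, S)` is the saturation concentration (umol/kg) in
#' equilibrium with the atmosphere. Water-vapour and hydrostatic pressure
#' corrections are neglected, which is adequate for upper-ocean climatology
#' use.
#'
#' @param conc Dissolved O2, umol/kg; must be >= 0.
#' @param T_C Temperature, degC, in \[-3, 40\].
#' @param S Practical salinity (default 35, open-ocean mean).
#' @return pO2, atm. Strictly linear (hence monotone) in `conc` at fixed
#'   `T_C`, `S`.
#' @seealso [po2_to_o2conc()] for the exact inverse.
#' @export
o2conc_to_po2 <- function(conc, T_C, S = 35) {
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("conc must be finite and >= 0")
  0.20946 * conc / o2_saturation(T_C, S)
}

#' @rdname o2conc_to_po2
#' @param pO2 O2 partial pressure, atm.
#' @export
po2_to_o2conc <- function(pO2, T_C, S = 35) {
  if (any(!is.finite(pO2)) || any(pO2 < 0))
    stop("pO2 must be finite and >= 0")
  pO2 * o2_saturation(T_C, S) / 0.20946
}

# Garcia & Gordon (1992) combined-fit O2 saturation, umol/kg
o2_saturation <- function(T_C, S = 35) {
  if (any(!is.finite(T_C)) || any(T_C < -3) || any(T_C > 40))
    stop("temperature outside supported range [-3, 40] degC")
  Ts <- log((298.15 - T_C) / (.T0K + T_C))
  A <- c(5.80871, 3.20291, 4.17887, 5.10006, -9.86643e-2, 3.80369)
  B <- c(-7.01577e-3, -7.70028e-3, -1.13864e-2, -9.51519e-3)
  C0 <- -2.75915e-7
  lnC <- A[1] + A[2] * Ts + A[3] * Ts^2 + A[4] * Ts^3 + A[5] * Ts^4 +
    A[6] * Ts^5 +
    S * (B[1] + B[2] * Ts + B[3] * Ts^2 + B[4] * Ts^3) + C0 * S^2
  exp(lnC)
}
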