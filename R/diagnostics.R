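#' Aerobic habitat volume for a trait combination
#'
#' Sums cell volume over ocean cells in a depth band whose Metabolic Index
#' lies in `[1, Phi_max]`. On monthly grids the monthly habitable volumes
#' are averaged. With `parts = TRUE` the sub-threshold (`Phi < 1`) and
#' super-band (`Phi > Phi_max`) volumes are also returned; the three parts
#' sum exactly to the band's total ocean volume.
#'
#' @param env An `env_grid`.
#' @param A_eco,E_eco_ref,dEdT,T_ref Trait values (see [trait_set()]).
#' @param Phi_max Upper bound of the habitable band; may be `Inf`.
#' @param depth_band `(top, bottom)` in metres; levels with
#'   `top <= depth < bottom` are included (the bottom edge is included for
#'   the deepest level).
#' @param parts Return the volume decomposition instead of a scalar.
#' @return Habitable volume in m^3, or a named list when `parts = TRUE`.
#' @export
habitat_volume <- function(env, A_eco, E_eco_ref, dEdT = 0.025,
                           Phi_max = 1.4, depth_band = c(0, 100),
                           T_ref = 15, parts = FALSE) {
  stopifnot(inherits(env, "env_grid"))
  if (!is.finite(Phi_max) && Phi_max < 0) stop("invalid Phi_max")
  if (Phi_max <= 1) stop("Phi_max must be > 1")
  ksel <- which(env$depth >= depth_band[1] & env$depth < depth_band[2])
  if (length(ksel) == 0 && max(env$depth) == depth_band[2])
    ksel <- length(env$depth)
  if (length(ksel) == 0)
    stop("no depth levels in band [", depth_band[1], ", ",
         depth_band[2], ")")
  traits <- trait_set(A_eco, E_eco_ref, dEdT, T_ref = T_ref,
                      allow_negative_dEdT = TRUE)
  vol <- env$volume[, , ksel, drop = FALSE]
  msk <- env$mask[, , ksel, drop = FALSE]
  nm <- dim(env$T)[4]
  acc <- c(habitable = 0, sub_threshold = 0, super_band = 0)
  for (m in seq_len(nm)) {
    Tm <- env$T[, , ksel, m, drop = FALSE]
    Pm <- env$pO2[, , ksel, m, drop = FALSE]
    phi <- metabolic_index(as.vector(Pm), as.vector(Tm), traits)
    v <- as.vector(vol)[as.vector(msk)]
    p <- phi[as.vector(msk)]
    acc["habitable"] <- acc["habitable"] +
      sum(v[p >= 1 & p <= Phi_max])
    acc["sub_threshold"] <- acc["sub_threshold"] + sum(v[p < 1])
    acc["super_band"] <- acc["super_band"] + sum(v[p > Phi_max])
  }
  acc <- acc / nm
  if (parts) as.list(c(acc, total = sum(vol[msk]))) else
    unname(acc["habitable"])
}

#' Habitat volume over a grid of trait combinations
#'
#' Vectorised evaluation of [habitat_volume()] over an `A_eco` x `E_eco_ref`
#' grid at fixed `dEdT`, for one or more depth bands (defaults: the warm
#' upper 100 m and the cooler 100-1000 m).
#'
#' @param env An `env_grid`.
#' @param A_grid,E_grid Trait axes.
#' @param dEdT Scalar slope, eV/degC (default 0.025).
#' @param Phi_max Upper bound of the habitable band.
#' @param bands List of `(top, bottom)` depth bands, m.
#' @param T_ref Reference temperature, degC.
#' @return A list (one element per band) of class `"habitat_volume_grid"`:
#'   `volume` matrix (A x E, m^3) plus the axes and metadata.
#' @export
habitat_volume_grid <- function(env, A_grid, E_grid, dEdT = 0.025,
                                Phi_max = 1.4,
                                bands = list(c(0, 100), c(100, 1000)),
                                T_ref = 15) {
  stopifnot(length(A_grid) >= 1, length(E_grid) >= 1)
  lapply(bands, function(band) {
    ksel <- which(env$depth >= band[1] & env$depth < band[2])
    if (length(ksel) == 0) stop("empty depth band")
    msk <- as.vector(env$mask[, , ksel, drop = FALSE])
    v <- as.vector(env$volume[, , ksel, drop = FALSE])[msk]
    nm <- dim(env$T)[4]
    vol <- matrix(0, length(A_grid), length(E_grid),
                  dimnames = list(NULL, NULL))
    for (m in seq_len(nm)) {
      Tm <- as.vector(env$T[, , ksel, m, drop = FALSE])[msk]
      Pm <- as.vector(env$pO2[, , ksel, m, drop = FALSE])[msk]
      for (ie in seq_along(E_grid)) {
        f <- arrhenius_factor(E_grid[ie] + dEdT * (Tm - T_ref), Tm, T_ref)
        for (ia in seq_along(A_grid)) {
          phi <- A_grid[ia] * Pm / f
          vol[ia, ie] <- vol[ia, ie] + sum(v[phi >= 1 & phi <= Phi_max])
        }
      }
    }
    structure(list(volume = vol / nm, A_grid = A_grid, E_grid = E_grid,
                   dEdT = dEdT, Phi_max = Phi_max, depth_band = band),
              class = "habitat_volume_grid")
  })
}

#' Temperature sensitivity of hypoxia tolerance at the range edges
#'
#' Evaluates the linear effective activation energy at a species' warm and
#' cold range edges: `E_ecoW,C = E_eco_ref + dEdT * (T_W,C - T_ref)`, where
#' `T_W`/`T_C` are the 95th/5th percentiles of inhabited temperature. The
#' difference `delta_E_eco = dEdT * (T_W - T_C)` holds exactly.
#'
#' @param fit A [fit_traits()] result, or any list with `traits`, `T_C`,
#'   `T_W`.
#' @return Named list `E_eco_W`, `E_eco_C`, `delta_E_eco` (eV).
#' @export
edge_sensitivities <- function(fit) {
  tr <- as_trait_set(fit$traits)
  if (is.null(fit$T_C) || is.null(fit$T_W))
    stop("fit must contain inhabited-temperature percentiles T_C, T_W")
  EW <- tr$E_eco_ref + tr$dEdT * (fit$T_W - tr$T_ref)
  EC <- tr$E_eco_ref + tr$dEdT * (fit$T_C - tr$T_ref)
  list(E_eco_W = EW, E_eco_C = EC, delta_E_eco = EW - EC)
}

#' Temperature sensitivity of the active-to-resting metabolic rate ratio
#'
#' The difference between biogeographically diagnosed and laboratory resting
#' temperature sensitivities: `E_phicrit = E_eco - E_o`, at the species
#' level.
#'
#' @param E_eco Diagnosed active temperature sensitivity, eV.
#' @param E_o Laboratory resting temperature sensitivity, eV.
#' @param species_eco,species_lab Optional species identifiers; when both
#'   are given they must match elementwise.
#' @return `E_phicrit`, eV. Vectorised.
#' @export
e_phicrit <- function(E_eco, E_o, species_eco = NULL, species_lab = NULL) {
  if (!is.null(species_eco) && !is.null(species_lab) &&
      any(species_eco != species_lab))
    stop("species mismatch between diagnosed and laboratory traits")
  if (any(!is.finite(E_eco)) || any(!is.finite(E_o)))
    stop("E_eco and E_o must be finite")
  E_eco - E_o
}

#' E_phicrit from factorial aerobic scope at multiple temperatures
#'
#' Fits an Arrhenius temperature dependence to laboratory FAS (= MMR/RMR)
#' measurements, a proxy for `Phi_crit`: the slope of `log(FAS)` against
#' `-(1/k_B) * (1/T_K - 1/Tref_K)` is the activation energy `E_phicrit`.
#' Declining FAS with warming yields a negative value.
#'
#' @param FAS Factorial aerobic scope values (> 0).
#' @param T_C Measurement temperatures, degC (>= 2 distinct).
#' @param T_ref Reference temperature, degC.
#' @return `E_phicrit`, eV.
#' @export
e_phicrit_from_fas <- function(FAS, T_C, T_ref = 15) {
  if (length(FAS) != length(T_C) || length(FAS) < 2)
    stop("need FAS at >= 2 temperatures")
  if (any(FAS <= 0)) stop("FAS must be > 0")
  if (length(unique(T_C)) < 2) stop("temperatures must differ")
  x <- -(1 / .kB) * (1 / (T_C + .T0K) - 1 / (T_ref + .T0K))
  unname(stats::coef(stats::lm(log(FAS) ~ x))[2])
}

#' Latitudinal summary of diagnosed traits
#'
#' Assigns each species its median occurrence latitude and summarises
#' `A_eco` and `E_eco_ref` per latitude band (median and the 10th/90th
#' deciles).
#'
#' @param trait_table Data frame with `species_id`, `A_eco`, `E_eco_ref`
#'   (as written by [fit_species_table()]).
#' @param occurrences Occurrence data frame with `species` and
#'   `decimalLatitude`.
#' @param band_width_deg Latitude band width, degrees.
#' @return Data frame of per-band trait quantiles plus species counts, with
#'   per-species median latitudes in the `"species_lat"` attribute.
#' @export
latitudinal_summary <- function(trait_table, occurrences,
                                band_width_deg = 10) {
  med_lat <- tapply(occurrences$decimalLatitude, occurrences$species,
                    stats::median)
  lat <- med_lat[trait_table$species_id]
  if (any(is.na(lat)))
    stop("species without occurrences: ",
         paste(trait_table$species_id[is.na(lat)], collapse = ", "))
  breaks <- seq(-90, 90, by = band_width_deg)
  band <- cut(lat, breaks, right = FALSE, include.lowest = TRUE)
  qs <- function(x, p) stats::quantile(x, p, type = 7, names = FALSE)
  agg <- function(v) do.call(rbind, tapply(v, band, function(x)
    c(q10 = qs(x, 0.1), median = qs(x, 0.5), q90 = qs(x, 0.9))))
  Aq <- agg(trait_table$A_eco)
  Eq <- agg(trait_table$E_eco_ref)
  keep <- !is.na(tapply(lat, band, length))
  out <- data.frame(
    band = levels(band)[keep],
    lat_mid = ((breaks[-length(breaks)] + breaks[-1]) / 2)[keep],
    n_species = as.integer(tapply(lat, band, length)[keep]),
    A_eco_q10 = Aq[, "q10"], A_eco_median = Aq[, "median"],
    A_eco_q90 = Aq[, "q90"],
    E_eco_q10 = Eq[, "q10"], E_eco_median = Eq[, "median"],
    E_eco_q90 = Eq[, "q90"], row.names = NULL)
  attr(out, "species_lat") <- med_lat
  out
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the supremum of the absolute difference between the two empirical
#' distribution functions; the p-value comes from the asymptotic Kolmogorov
#' distribution with Stephens' effective-sample-size correction
#' `lambda = (sqrt(ne) + 0.12 + 0.11/sqrt(ne)) * D`, `ne = n m / (n + m)`.
#'
#' @param x,y Numeric samples (each non-empty).
#' @return List with `D`, `p`, and the sample sizes.
#' @export
ks_two_sample <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n <- length(x); m <- length(y)
  if (n < 1 || m < 1) stop("both samples must be non-empty")
  z <- c(x, y)
  o <- order(z, c(rep(1L, n), rep(2L, m)))  # stable across ties
  steps <- ifelse(c(rep(1L, n), rep(2L, m))[o] == 1L, 1 / n, -1 / m)
  cdf_diff <- cumsum(steps)
  # at tied values only the completed step counts
  zo <- z[o]
  last_of_run <- c(zo[-1] != zo[-length(zo)], TRUE)
  D <- max(abs(cdf_diff[last_of_run]))
  ne <- n * m / (n + m)
  lambda <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * D
  k <- 1:101
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  list(D = D, p = min(max(p, 0), 1), n = n, m = m)
}
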