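#' Ground truth for a synthetic species
#'
#' Pairs a true [trait_set()] with the sampling conditions used by
#' [simulate_species()]: the occupied Metabolic Index band, the number of
#' occurrence records and the label-noise rate.
#'
#' @param traits True [trait_set()].
#' @param Phi_max Upper bound of the occupied index band, > 1. The default
#'   `Inf` makes the species lower-threshold-limited: it occupies all
#'   metabolically viable water, and its occupied Phi_max emerges from what
#'   the ocean offers above the threshold (as diagnosed values do). Set a
#'   finite value to restrict occupancy to an index band.
#' @param n_presence Number of occurrence records to draw.
#' @param noise_rate Fraction of records flipped to a uniformly random
#'   non-habitat cell, in \[0, 0.5).
#' @param seed Integer seed making the draw reproducible.
#' @param species_id Identifier; defaults to the trait set's.
#' @return Object of class `"species_truth"`.
#' @export
species_truth <- function(traits, Phi_max = Inf, n_presence = 500,
                          noise_rate = 0.05, seed = 1,
                          species_id = traits$species_id) {
  traits <- as_trait_set(traits)
  if (is.na(Phi_max) || Phi_max <= 1) stop("Phi_max must be > 1")
  if (noise_rate < 0 || noise_rate >= 0.5)
    stop("noise_rate must be in [0, 0.5)")
  if (n_presence < 1) stop("n_presence must be >= 1")
  structure(list(species_id = species_id, traits = traits,
                 Phi_max = Phi_max, n_presence = as.integer(n_presence),
                 noise_rate = noise_rate, seed = as.integer(seed)),
            class = "species_truth")
}

# TRUE when a species' lower pO2 threshold is expressed in the ocean well
# enough for its traits to be recoverable from occupancy: enough habitat
# cells; habitable and sub-threshold water coexisting in most inhabited
# temperature bins; and that coexistence spanning a wide-enough temperature
# lever that reaches near the reference temperature (with a one-sided,
# narrow or far-from-reference lever, E_eco_ref is an extrapolation and
# E/dEdT are collinear, so no occupancy-based method can pin them down)
is_diagnosable <- function(env, traits, Phi_max = Inf,
                           min_habitat_cells = 50, bite_frac = 0.7,
                           bite_span_min = 8, ref_reach = 5, T_bin = 2) {
  phi <- phi_field(env, traits)
  ann <- annual_mean_fields(env)
  ocean <- env$mask
  hab <- ocean & phi >= 1 & phi <= Phi_max
  if (sum(hab) < min_habitat_cells) return(FALSE)
  sub <- ocean & phi < 1
  Th <- ann$T[hab]
  qT <- stats::quantile(Th, c(0.05, 0.95), type = 7, names = FALSE)
  edges <- seq(floor(qT[1] / T_bin) * T_bin,
               ceiling(qT[2] / T_bin) * T_bin, by = T_bin)
  if (length(edges) < 2) return(FALSE)
  bh <- table(cut(Th, edges))
  bs <- table(cut(ann$T[sub], edges))
  both <- bh > 0 & bs > 0
  inhabited <- sum(bh > 0)
  if (inhabited == 0 || sum(both) / inhabited < bite_frac) return(FALSE)
  mids <- (edges[-length(edges)] + edges[-1]) / 2
  bite_T <- mids[both]
  diff(range(bite_T)) >= bite_span_min &&
    min(abs(bite_T - traits$T_ref)) <= ref_reach
}

# Metabolic index over all grid cells at the annual-mean fields,
# returned as a (lon, lat, depth) array
phi_field <- function(env, traits) {
  fl <- annual_mean_fields(env)
  arr <- metabolic_index(as.vector(fl$pO2), as.vector(fl$T), traits)
  array(arr, dim = dim(env$volume))
}

#' Simulate occurrence records for a species with known traits
#'
#' Draws `n_presence` occurrence records from the species' aerobic habitat:
#' grid cells where the true Metabolic Index satisfies
#' `1 <= Phi <= Phi_max`. Cells are sampled with replacement with
#' probability proportional to cell volume; each record is then flipped,
#' with probability `noise_rate`, to a uniformly random non-habitat ocean
#' cell (a simple misdetection model). Positions are jittered uniformly
#' within the cell so records resemble point observations.
#'
#' @param env An [make_ocean()] grid.
#' @param truth A [species_truth()].
#' @return A data.frame of Darwin Core-like records: `species`,
#'   `decimalLatitude`, `decimalLongitude`, `depth`, `month` (NA on annual
#'   grids). Deterministic given `truth$seed`.
#' @export
simulate_species <- function(env, truth) {
  stopifnot(inherits(env, "env_grid"), inherits(truth, "species_truth"))
  phi <- phi_field(env, truth$traits)
  ocean <- env$mask
  habitat <- which(ocean & phi >= 1 & phi <= truth$Phi_max)
  if (length(habitat) == 0L)
    stop(sprintf(paste0("empty habitat for species '%s' ",
                        "(A_eco = %.3g, E_eco_ref = %.3g, dEdT = %.3g, ",
                        "Phi_max = %.3g): no ocean cell has 1 <= Phi <= ",
                        "Phi_max"),
                 truth$species_id, truth$traits$A_eco,
                 truth$traits$E_eco_ref, truth$traits$dEdT, truth$Phi_max))
  nonhab <- which(ocean & !(phi >= 1 & phi <= truth$Phi_max))

  n <- truth$n_presence
  dims <- dim(env$volume)
  res <- env$resolution_deg
  monthly <- length(env$month) > 1L

  .with_seed(truth$seed, {
    w <- env$volume[habitat]
    cells <- habitat[sample.int(length(habitat), n, replace = TRUE,
                                prob = w / sum(w))]
    if (truth$noise_rate > 0 && length(nonhab) > 0) {
      flip <- stats::runif(n) < truth$noise_rate
      if (any(flip))
        cells[flip] <- nonhab[sample.int(length(nonhab), sum(flip),
                                         replace = TRUE)]
    }
    idx <- arrayInd(cells, dims)
    lat0 <- env$lat[idx[, 2]] - res / 2
    lon0 <- env$lon[idx[, 1]] - res / 2
    data.frame(
      species = truth$species_id,
      decimalLatitude = lat0 + stats::runif(n) * res,
      decimalLongitude = lon0 + stats::runif(n) * res,
      depth = env$depth[idx[, 3]],
      month = if (monthly) sample(1:12, n, replace = TRUE) else NA_integer_,
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate a multi-species assemblage with known ground truth
#'
#' Draws `n_species` trait sets (A_eco log-uniform, E_eco_ref and dEdT
#' uniform over the given ranges) and simulates occurrences for each.
#' Draws are rejected when the resulting species would not be diagnosable
#' from biogeography on `env`: its aerobic habitat must hold at least
#' `min_habitat_cells` cells (a species with no habitat produces no
#' records), and its lower pO2 threshold must be expressed in the
#' environment - across the habitat's inhabited temperature range, at least
#' a fraction `bite_frac` of temperature bins must contain both habitable
#' and sub-threshold water. A species whose threshold curve everywhere
#' undercuts (or everywhere exceeds) the ocean's pO2 range has no observed
#' lower edge, so its traits are not recoverable from occupancy by any
#' method; such species are excluded from the ground-truth set by design.
#'
#' @param env An [make_ocean()] grid.
#' @param n_species Number of species.
#' @param A_range,E_range,dEdT_range Trait ranges (A sampled log-uniformly).
#' @param Phi_max,n_presence,noise_rate Passed to [species_truth()].
#' @param min_habitat_cells Minimum habitat size for an accepted draw.
#' @param bite_frac Minimum fraction of inhabited 2 degC temperature bins in
#'   which the threshold separates habitable from sub-threshold water.
#' @param seed Master seed; per-species seeds are derived from it.
#' @return List with `occurrences` (row-bound records of all species),
#'   `truth` (data.frame of true traits) and `truths` (list of
#'   [species_truth()] objects).
#' @export
simulate_assemblage <- function(env, n_species = 20,
                                A_range = c(0.5, 100),
                                E_range = c(-1, 2),
                                dEdT_range = c(0, 0.12),
                                Phi_max = Inf, n_presence = 500,
                                noise_rate = 0.05,
                                min_habitat_cells = 50, bite_frac = 0.7,
                                seed = 1) {
  truths <- vector("list", n_species)
  draws <- .with_seed(seed, {
    # oversample candidate traits; rejection happens deterministically below
    nmax <- n_species * 500L
    data.frame(
      A = exp(stats::runif(nmax, log(A_range[1]), log(A_range[2]))),
      E = stats::runif(nmax, E_range[1], E_range[2]),
      D = stats::runif(nmax, dEdT_range[1], dEdT_range[2])
    )
  })
  k <- 0L
  for (i in seq_len(nrow(draws))) {
    if (k >= n_species) break
    tr <- trait_set(draws$A[i], draws$E[i], draws$D[i],
                    species_id = sprintf("syn%03d", k + 1L))
    if (is_diagnosable(env, tr, Phi_max, min_habitat_cells, bite_frac)) {
      k <- k + 1L
      truths[[k]] <- species_truth(tr, Phi_max = Phi_max,
                                   n_presence = n_presence,
                                   noise_rate = noise_rate,
                                   seed = seed + k)
    }
  }
  if (k < n_species)
    stop("could not find ", n_species, " trait draws with habitat >= ",
         min_habitat_cells, " cells (got ", k, ")")
  occ <- do.call(rbind, lapply(truths, simulate_species, env = env))
  truth_tab <- do.call(rbind, lapply(truths, function(s)
    data.frame(species_id = s$species_id, A_eco = s$traits$A_eco,
               E_eco_ref = s$traits$E_eco_ref, dEdT = s$traits$dEdT,
               T_ref = s$traits$T_ref, Phi_max = s$Phi_max,
               n_presence = s$n_presence, noise_rate = s$noise_rate,
               seed = s$seed, stringsAsFactors = FALSE)))
  list(occurrences = occ, truth = truth_tab, truths = truths)
}
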