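#' F1-score from confusion counts
#'
#' `2 TP / (2 TP + FP + FN)`, the harmonic mean of precision and recall.
#' Defined as 0 when `TP = 0` and errors are present; 1 for a perfect
#' classifier.
#'
#' @param TP,FP,FN Non-negative (possibly weighted) counts.
#' @return F1 in \[0, 1\]. Vectorised.
#' @export
f1_score <- function(TP, FP, FN) {
  if (any(c(TP, FP, FN) < 0)) stop("counts must be >= 0")
  if (any(TP + FP + FN == 0))
    stop("undefined F1: all of TP, FP, FN are zero")
  ifelse(TP > 0, 2 * TP / (2 * TP + FP + FN), 0)
}

#' Classify an occupancy dataset at given traits
#'
#' Predicts a sample habitable when its Metabolic Index is at least 1 and
#' tallies the confusion counts against the presence/background labels.
#'
#' @param dataset An [build_occupancy()] result.
#' @param traits A [trait_set()].
#' @param weighting `"count"` (cell counts, default) or `"volume"`.
#' @return Named list `TP`, `FP`, `FN`, `TN`.
#' @export
classify <- function(dataset, traits, weighting = c("count", "volume")) {
  weighting <- match.arg(weighting)
  if (dataset$skipped) stop("dataset was skipped: ", dataset$skip_reason)
  s <- dataset$samples
  phi <- metabolic_index(s$pO2, s$T, traits)
  hab <- phi >= 1
  w <- if (weighting == "volume") s$volume else s$weight
  pres <- s$label == "presence"
  list(TP = sum(w[pres & hab]), FP = sum(w[!pres & hab]),
       FN = sum(w[pres & !hab]), TN = sum(w[!pres & !hab]))
}

#' Search grid for trait fitting
#'
#' Defaults span the trait ranges seen across marine ectotherms: `A_eco`
#' log-spaced over 0.5-100 atm^-1 (40 points), `E_eco_ref` from -1 to 2 eV
#' in 0.05 eV steps, `dEdT` from 0 to 0.12 eV/degC in 0.01 steps, followed
#' by one local refinement pass at `refine`-fold resolution around the
#' coarse optimum.
#'
#' @param A_grid,E_grid,dEdT_grid Numeric axes. Set `dEdT_grid = 0` to fit
#'   without the temperature-varying slope.
#' @param refine Refinement factor (default 5); 0 disables refinement.
#' @param plateau Plateau tolerance in reclassification units: grid points
#'   whose F1 lies within `plateau / (2 * total presence weight)` of the
#'   maximum are statistically indistinguishable from it (moving one
#'   unit-weight sample across the threshold changes F1 by about that
#'   much), and the fit reports the centroid of that near-optimal set
#'   (geometric mean of `A_eco`, arithmetic means of `E_eco_ref`, `dEdT`)
#'   rather than an arbitrary vertex of the plateau. 0 restricts the set to
#'   exact ties.
#' @return A list of class `"search_spec"`.
#' @export
search_spec <- function(A_grid = exp(seq(log(0.5), log(100),
                                         length.out = 40)),
                        E_grid = seq(-1, 2, by = 0.05),
                        dEdT_grid = seq(0, 0.12, by = 0.01),
                        refine = 5, plateau = 2) {
  stopifnot(all(A_grid > 0), !is.unsorted(A_grid, strictly = TRUE),
            length(E_grid) >= 1, length(dEdT_grid) >= 1, refine >= 0,
            plateau >= 0)
  structure(list(A_grid = A_grid, E_grid = sort(E_grid),
                 dEdT_grid = sort(dEdT_grid), refine = refine,
                 plateau = plateau),
            class = "search_spec")
}

# Evaluate F1 over a full (A, E, dEdT) grid. Returns the flat table of grid
# points with their F1, ordered as evaluated. The per-sample Metabolic Index
# is computed with the same arithmetic as metabolic_index() so grid and
# pointwise classification agree bit for bit.
eval_f1_grid <- function(samples, A_grid, E_grid, D_grid, T_ref, weighting) {
  w <- if (weighting == "volume") samples$volume else samples$weight
  pres <- samples$label == "presence"
  wp <- w * pres
  wb <- w * !pres
  P <- sum(wp)
  if (sum(wb) == 0) stop("degenerate dataset: no background samples")
  Tv <- samples$T
  pO2 <- samples$pO2
  nA <- length(A_grid)
  M0 <- outer(pO2, A_grid)  # A_eco * pO2, exact by commutativity
  out <- vector("list", length(E_grid) * length(D_grid))
  idx <- 0L
  for (D in D_grid) for (E in E_grid) {
    f <- arrhenius_factor(E + D * (Tv - T_ref), Tv, T_ref)
    hab <- (M0 / f) >= 1
    TP <- as.vector(crossprod(hab, wp))
    FP <- as.vector(crossprod(hab, wb))
    FN <- P - TP
    F1 <- ifelse(TP > 0, 2 * TP / (2 * TP + FP + FN), 0)
    idx <- idx + 1L
    out[[idx]] <- data.frame(A = A_grid, E = E, D = D, F1 = F1)
  }
  do.call(rbind, out)
}

# deterministic argmax vertex: highest F1, then lowest A, then E nearest 0,
# then lowest dEdT, then lowest E
pick_best <- function(tab) {
  tab[order(-tab$F1, tab$A, abs(tab$E), tab$D, tab$E)[1], ]
}

# centroid of the near-optimal plateau (see search_spec); row order of tab
# is the evaluation order, making the means reproducible exactly
plateau_centroid <- function(tab, tol) {
  near <- tab[tab$F1 >= max(tab$F1) - tol, ]
  data.frame(A = exp(mean(log(near$A))), E = mean(near$E),
             D = mean(near$D), F1 = max(near$F1), n_plateau = nrow(near))
}

# refined axis: centre +/- one coarse step at finer resolution, clamped to
# the coarse axis range
refine_axis <- function(grid, value, n, log_scale = FALSE) {
  if (length(grid) == 1L) return(grid)
  if (log_scale) {
    step <- stats::median(diff(log(grid)))
    v <- exp(seq(log(value) - step, log(value) + step, length.out = n))
  } else {
    step <- stats::median(diff(grid))
    v <- seq(value - step, value + step, length.out = n)
  }
  unique(pmin(pmax(v, min(grid)), max(grid)))
}

#' Diagnose active hypoxia traits by maximising the F1-score
#'
#' Exhaustive grid search over (`A_eco`, `E_eco_ref`, `dEdT`) for the traits
#' whose habitability classifier (`Phi >= 1`) best separates presence from
#' background samples. Because the F1 surface is a step function, the raw
#' argmax is an arbitrary vertex of a flat near-optimal region; the fit
#' instead reports the centroid of that plateau (see the `plateau` argument
#' of [search_spec()]), then runs one local refinement pass at
#' `refine`-fold resolution around it. Fully deterministic.
#'
#' @param dataset An [build_occupancy()] result.
#' @param search A [search_spec()].
#' @param weighting `"count"` or `"volume"` confusion weighting.
#' @param T_ref Reference temperature of the fitted traits, degC.
#' @return Object of class `"fit_result"`: `traits` ([trait_set()]), `F1`,
#'   `confusion` (TP/FP/FN/TN), `T_C`/`T_W` (5th/95th percentile inhabited
#'   temperature), `Phi_max` (95th percentile Metabolic Index over presence
#'   cells at the fitted traits), `n_cells`, `flag`.
#' @export
fit_traits <- function(dataset, search = search_spec(),
                       weighting = c("count", "volume"), T_ref = 15) {
  weighting <- match.arg(weighting)
  if (dataset$skipped) stop("dataset was skipped: ", dataset$skip_reason)
  s <- dataset$samples

  wgt <- if (weighting == "volume") s$volume else s$weight
  P <- sum(wgt[s$label == "presence"])
  tol <- search$plateau / (2 * P)

  coarse <- eval_f1_grid(s, search$A_grid, search$E_grid, search$dEdT_grid,
                         T_ref, weighting)
  best <- plateau_centroid(coarse, tol)

  if (search$refine > 0) {
    n <- 2L * search$refine + 1L
    A_f <- refine_axis(search$A_grid, best$A, n, log_scale = TRUE)
    E_f <- refine_axis(search$E_grid, best$E, n)
    D_f <- refine_axis(search$dEdT_grid, best$D, n)
    fine <- eval_f1_grid(s, A_f, E_f, D_f, T_ref, weighting)
    best <- plateau_centroid(fine, tol)
  }

  traits <- trait_set(best$A, best$E, best$D, T_ref = T_ref,
                      species_id = dataset$species_id,
                      allow_negative_dEdT = TRUE)
  conf <- classify(dataset, traits, weighting)
  qT <- stats::quantile(dataset$presence_cells$T, c(0.05, 0.95), type = 7,
                        names = FALSE)
  phimax <- phi_max_ratio(dataset, traits)

  structure(list(
    traits = traits, F1 = f1_score(conf$TP, conf$FP, conf$FN),
    confusion = conf, T_C = qT[1], T_W = qT[2], Phi_max = phimax,
    n_cells = dataset$n_presence_cells,
    flag = if (f1_score(conf$TP, conf$FP, conf$FN) >= 0.5) "ok"
           else "low_skill"),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Trait fit [%s]: F1 = %.3f (%s)\n", x$traits$species_id,
              x$F1, x$flag))
  cat(sprintf("  A_eco = %.3g atm^-1, E_eco_ref = %.3g eV, dEdT = %.3g\n",
              x$traits$A_eco, x$traits$E_eco_ref, x$traits$dEdT))
  cat(sprintf("  inhabited T: %.1f-%.1f degC; Phi_max = %.2f; %d cells\n",
              x$T_C, x$T_W, x$Phi_max, x$n_cells))
  invisible(x)
}

#' Occupied Metabolic Index headroom
#'
#' The 95th percentile (linear interpolation between closest ranks) of the
#' Metabolic Index over a species' presence cells at the given traits. Since
#' the fitted threshold is `Phi = 1` (i.e. the index is normalised by
#' `Phi_crit`), this is the occupied `Phi_max / Phi_crit` ratio.
#'
#' @param dataset An [build_occupancy()] result.
#' @param traits A [trait_set()] (typically the fitted traits).
#' @param prob Upper percentile (default 0.95).
#' @return Dimensionless ratio.
#' @export
phi_max_ratio <- function(dataset, traits, prob = 0.95) {
  if (dataset$skipped) stop("dataset was skipped: ", dataset$skip_reason)
  pres <- dataset$presence_cells
  phi <- metabolic_index(pres$pO2, pres$T, traits)
  stats::quantile(phi, prob, type = 7, names = FALSE)
}

#' Empirical lower pO2 envelope of presence samples
#'
#' A low quantile (default the 5th percentile) of presence pO2 per
#' temperature bin: the observed lower threshold above which occurrences are
#' common and below which they are rare. Used for initial inspection and
#' plotting, not by the fit itself.
#'
#' @param dataset An [build_occupancy()] result.
#' @param T_breaks Temperature bin edges, degC.
#' @param prob Quantile level (default 0.05).
#' @return Data frame with bin edges/midpoints, occupied-cell counts and the
#'   pO2 envelope (`NA` where a bin holds no presence cells).
#' @export
empirical_lower_threshold <- function(dataset,
                                      T_breaks = NULL, prob = 0.05) {
  if (dataset$skipped) stop("dataset was skipped: ", dataset$skip_reason)
  pres <- dataset$presence_cells
  Tv <- pres$T
  pv <- pres$pO2
  if (is.null(T_breaks))
    T_breaks <- seq(floor(min(Tv)), ceiling(max(Tv)) + 1, by = 2)
  bin <- cut(Tv, T_breaks, right = FALSE, include.lowest = TRUE)
  q <- tapply(pv, bin, stats::quantile, probs = prob, type = 7,
              names = FALSE)
  n <- tapply(pv, bin, length)
  data.frame(T_lo = T_breaks[-length(T_breaks)], T_hi = T_breaks[-1],
             T_mid = (T_breaks[-length(T_breaks)] + T_breaks[-1]) / 2,
             n_cells = as.integer(ifelse(is.na(n), 0L, n)),
             po2_lower = as.numeric(q))
}

#' Fit traits for every species in an occurrence table
#'
#' Convenience driver: splits a multi-species occurrence table, builds each
#' occupancy dataset, applies the minimum-cells gate and fits traits.
#'
#' @param occurrences Multi-species occurrence data frame (with a `species`
#'   column).
#' @param env An `env_grid`.
#' @param opts See [occupancy_opts()].
#' @param search See [search_spec()].
#' @param weighting,T_ref Passed to [fit_traits()].
#' @param verbose Print one line per species.
#' @return Data frame (one row per fitted species) with columns
#'   `species_id, A_eco, E_eco_ref, dEdT, F1, TP, FP, FN, TN, T_C, T_W,
#'   Phi_max, n_cells, flag`; skipped species are reported in the
#'   `"skipped"` attribute.
#' @export
fit_species_table <- function(occurrences, env, opts = occupancy_opts(),
                              search = search_spec(),
                              weighting = "count", T_ref = 15,
                              verbose = FALSE) {
  sps <- unique(occurrences$species)
  rows <- list(); skips <- list()
  for (sp in sps) {
    ds <- build_occupancy(occurrences[occurrences$species == sp, ],
                          env, opts)
    if (ds$skipped) {
      skips[[sp]] <- ds$skip_reason
      if (verbose) message(sp, ": skipped (", ds$skip_reason, ")")
      next
    }
    fit <- fit_traits(ds, search, weighting, T_ref)
    if (verbose)
      message(sprintf("%s: F1 = %.3f, A_eco = %.3g, E = %.3g, dEdT = %.3g",
                      sp, fit$F1, fit$traits$A_eco, fit$traits$E_eco_ref,
                      fit$traits$dEdT))
    rows[[sp]] <- data.frame(
      species_id = sp, A_eco = fit$traits$A_eco,
      E_eco_ref = fit$traits$E_eco_ref, dEdT = fit$traits$dEdT,
      F1 = fit$F1, TP = fit$confusion$TP, FP = fit$confusion$FP,
      FN = fit$confusion$FN, TN = fit$confusion$TN,
      T_C = fit$T_C, T_W = fit$T_W, Phi_max = fit$Phi_max,
      n_cells = fit$n_cells, flag = fit$flag, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(species_id = character(0))
  rownames(out) <- NULL
  attr(out, "skipped") <- skips
  out
}
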