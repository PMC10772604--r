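#' Options controlling occurrence-to-grid matching
#'
#' @param min_cells Minimum number of unique occupied cells below which a
#'   species is skipped rather than fitted (default 10).
#' @param depth_pad_levels Background domain: the species' occupied
#'   depth-level range is extended by this many levels on each side.
#' @param lat_pad_deg Optional latitude-band envelope for the background
#'   domain: presence latitude range padded by this many degrees. `NULL`
#'   (default) uses all latitudes, the documented global default.
#' @param missing_depth How to treat records without depth: `"surface"`
#'   assigns the shallowest level, `"drop"` discards them.
#' @param universe Fitting universe. `"state_bins"` (default): occupancy is
#'   evaluated on a binned temperature-pO2 state space, the projection in
#'   which the lower-threshold curve is actually identified - a bin is a
#'   presence sample when at least one occupied cell maps into it, a
#'   background sample when only unoccupied water does. `"cells"`: the raw
#'   geographic-cell universe (one unit of weight per grid cell).
#' @param T_bin_width Temperature bin width, degC (state-bin universe).
#' @param pO2_bin_ratio Multiplicative pO2 bin width (state-bin universe);
#'   1.03 gives ~3% resolution at every pO2 level.
#' @return A list of options for [build_occupancy()].
#' @export
occupancy_opts <- function(min_cells = 10, depth_pad_levels = 1,
                           lat_pad_deg = NULL,
                           missing_depth = c("surface", "drop"),
                           universe = c("state_bins", "cells"),
                           T_bin_width = 1, pO2_bin_ratio = 1.03) {
  missing_depth <- match.arg(missing_depth)
  universe <- match.arg(universe)
  stopifnot(T_bin_width > 0, pO2_bin_ratio > 1)
  list(min_cells = min_cells, depth_pad_levels = depth_pad_levels,
       lat_pad_deg = lat_pad_deg, missing_depth = missing_depth,
       universe = universe, T_bin_width = T_bin_width,
       pO2_bin_ratio = pO2_bin_ratio)
}

#' Project occurrence records onto temperature-pO2 state space
#'
#' Snaps each record to its containing grid cell (half-open lon/lat
#' intervals, nearest depth level; month-resolved on monthly grids when the
#' record carries a month, annual mean otherwise). Presence cells are the
#' unique occupied cells; the background is every other ocean cell within
#' the background domain (occupied depth range padded by
#' `depth_pad_levels`, optional latitude band). The fitting samples are then
#' built in the configured universe (see [occupancy_opts()]): binned T-pO2
#' state space by default, or raw cells. Cells with identical (T, pO2)
#' collapse into one weighted sample either way, so all counts stay exact.
#'
#' @param occurrences Data frame with `decimalLatitude`, `decimalLongitude`
#'   and optionally `depth`, `month`, `species` (single species).
#' @param env An `env_grid`.
#' @param opts See [occupancy_opts()].
#' @return Object of class `"occupancy"` with elements `species_id`,
#'   `samples` (data.frame: `T`, `pO2`, `label`, `weight`, `volume`),
#'   `presence_cells` (per unique occupied cell: `T`, `pO2`, `volume`),
#'   `n_presence_cells`, `counts` (provenance), `universe`, `skipped`,
#'   `skip_reason`.
#' @export
build_occupancy <- function(occurrences, env, opts = occupancy_opts()) {
  stopifnot(inherits(env, "env_grid"))
  if (nrow(occurrences) == 0L) stop("no occurrence records")
  sp <- if ("species" %in% names(occurrences))
    unique(occurrences$species) else NA_character_
  if (length(sp) > 1L)
    stop("build_occupancy takes one species at a time; got ",
         length(sp), " species")

  res <- env$resolution_deg
  nlon <- length(env$lon); nlat <- length(env$lat); nz <- length(env$depth)
  monthly <- length(env$month) > 1L
  n_read <- nrow(occurrences)

  lat <- occurrences$decimalLatitude
  lon <- occurrences$decimalLongitude
  ok <- is.finite(lat) & is.finite(lon) & lat >= -90 & lat <= 90
  n_badcoord <- sum(!ok)
  lat <- lat[ok]; lon <- lon[ok]
  lon <- ((lon + 180) %% 360) - 180
  dep <- if ("depth" %in% names(occurrences)) occurrences$depth[ok]
         else rep(NA_real_, length(lat))
  mon <- if ("month" %in% names(occurrences)) occurrences$month[ok]
         else rep(NA_integer_, length(lat))

  if (opts$missing_depth == "drop") {
    keep <- is.finite(dep)
    n_nodepth <- sum(!keep)
    lat <- lat[keep]; lon <- lon[keep]; dep <- dep[keep]; mon <- mon[keep]
  } else n_nodepth <- 0L

  i <- pmin(floor((lon + 180) / res) + 1L, nlon)
  j <- pmin(floor((lat + 90) / res) + 1L, nlat)
  k <- vapply(dep, function(d) {
    if (!is.finite(d)) 1L else which.min(abs(env$depth - d))
  }, integer(1))
  m <- ifelse(monthly & is.finite(mon) & mon >= 1 & mon <= 12,
              as.integer(mon), 0L)  # 0 = annual mean

  on_ocean <- env$mask[cbind(i, j, k)]
  n_land <- sum(!on_ocean)
  i <- i[on_ocean]; j <- j[on_ocean]; k <- k[on_ocean]; m <- m[on_ocean]

  key <- paste(i, j, k, m)
  uk <- !duplicated(key)
  ci <- i[uk]; cj <- j[uk]; ck <- k[uk]; cm <- m[uk]
  n_cells_presence <- length(ci)

  counts <- list(records_read = n_read, dropped_coords = n_badcoord,
                 dropped_no_depth = n_nodepth, dropped_land = n_land,
                 matched = length(i), presence_cells = n_cells_presence)

  if (n_cells_presence < opts$min_cells) {
    return(structure(list(species_id = sp, samples = NULL,
                          presence_cells = NULL,
                          n_presence_cells = n_cells_presence,
                          counts = counts, universe = opts$universe,
                          skipped = TRUE,
                          skip_reason = sprintf(
                            "min_cells: %d unique cells < %d",
                            n_cells_presence, opts$min_cells)),
                     class = "occupancy"))
  }

  ann <- annual_mean_fields(env)
  getT <- function(i, j, k, m)
    ifelse(m == 0L, ann$T[cbind(i, j, k)], env$T[cbind(i, j, k, pmax(m, 1L))])
  getP <- function(i, j, k, m)
    ifelse(m == 0L, ann$pO2[cbind(i, j, k)],
           env$pO2[cbind(i, j, k, pmax(m, 1L))])

  presence <- data.frame(
    T = getT(ci, cj, ck, cm), pO2 = getP(ci, cj, ck, cm),
    volume = env$volume[cbind(ci, cj, ck)])

  # background domain: ocean cells in the padded depth band (and optional
  # latitude band), excluding every physically occupied (lon, lat, depth)
  krange <- range(ck)
  kmin <- max(1L, krange[1] - opts$depth_pad_levels)
  kmax <- min(nz, krange[2] + opts$depth_pad_levels)
  jset <- seq_len(nlat)
  if (!is.null(opts$lat_pad_deg)) {
    lrange <- range(env$lat[cj]) + c(-1, 1) * opts$lat_pad_deg
    jset <- which(env$lat >= lrange[1] & env$lat <= lrange[2])
  }
  grid_idx <- expand.grid(i = seq_len(nlon), j = jset, k = kmin:kmax)
  occ3 <- unique(paste(ci, cj, ck))
  bg <- grid_idx[env$mask[as.matrix(grid_idx)] &
                   !(paste(grid_idx$i, grid_idx$j, grid_idx$k) %in% occ3), ]

  mslots <- if (monthly) 1:12 else 0L
  bglist <- lapply(mslots, function(ms) data.frame(
    T = getT(bg$i, bg$j, bg$k, rep(ms, nrow(bg))),
    pO2 = getP(bg$i, bg$j, bg$k, rep(ms, nrow(bg))),
    volume = env$volume[as.matrix(bg)]))
  background <- do.call(rbind, bglist)

  samples <- switch(
    opts$universe,
    cells = rbind(.collapse_cells(presence, "presence"),
                  .collapse_cells(background, "background")),
    state_bins = .bin_state_space(presence, background,
                                  opts$T_bin_width, opts$pO2_bin_ratio))
  rownames(samples) <- NULL

  structure(list(species_id = sp, samples = samples,
                 presence_cells = presence,
                 n_presence_cells = n_cells_presence,
                 counts = counts, universe = opts$universe,
                 skipped = FALSE, skip_reason = NA_character_),
            class = "occupancy")
}

# one weighted sample per distinct (T, pO2) value; weight = cell count
.collapse_cells <- function(df, label) {
  g <- paste(df$T, df$pO2)  # exact string form groups identical doubles
  first <- !duplicated(g)
  agg <- data.frame(T = df$T[first], pO2 = df$pO2[first])
  agg$label <- label
  gu <- g[first]
  agg$weight <- as.numeric(table(g)[gu])
  agg$volume <- as.numeric(tapply(df$volume, g, sum)[gu])
  agg
}

# one sample per occupied T-pO2 state-space bin; a bin is presence when any
# occupied cell maps into it; samples sit at bin centres with unit weight
.bin_state_space <- function(presence, background, T_bin_width,
                             pO2_bin_ratio) {
  allT <- c(presence$T, background$T)
  allP <- c(presence$pO2, background$pO2)
  allP <- pmax(allP, 1e-6)  # guard log binning against pO2 = 0 cells
  T_edges <- seq(floor(min(allT) / T_bin_width) * T_bin_width,
                 ceiling(max(allT) / T_bin_width) * T_bin_width +
                   T_bin_width, by = T_bin_width)
  lr <- log(pO2_bin_ratio)
  p_lo <- floor(log(min(allP)) / lr)
  p_hi <- ceiling(log(max(allP)) / lr) + 1
  P_edges <- exp(seq(p_lo, p_hi) * lr)
  bt <- findInterval(allT, T_edges, rightmost.closed = TRUE)
  bp <- findInterval(allP, P_edges, rightmost.closed = TRUE)
  is_pres <- c(rep(TRUE, nrow(presence)), rep(FALSE, nrow(background)))
  vol <- c(presence$volume, background$volume)
  g <- paste(bt, bp)
  first <- !duplicated(g)
  gu <- g[first]
  occupied <- tapply(is_pres, g, any)[gu]
  data.frame(
    T = (T_edges[bt[first]] + T_edges[bt[first] + 1L]) / 2,
    pO2 = sqrt(P_edges[bp[first]] * P_edges[bp[first] + 1L]),
    label = ifelse(occupied, "presence", "background"),
    weight = 1,
    volume = as.numeric(tapply(vol, g, sum)[gu]))
}

#' @export
print.occupancy <- function(x, ...) {
  if (x$skipped) {
    cat(sprintf("Occupancy [%s]: SKIPPED (%s)\n", x$species_id,
                x$skip_reason))
  } else {
    np <- sum(x$samples$weight[x$samples$label == "presence"])
    nb <- sum(x$samples$weight[x$samples$label == "background"])
    cat(sprintf(
      "Occupancy [%s]: %d occupied cells; universe '%s': %g presence + %g background samples\n",
      x$species_id, x$n_presence_cells, x$universe, np, nb))
  }
  invisible(x)
}
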