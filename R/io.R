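#' Read and validate an occurrence CSV
#'
#' Darwin Core-like schema: required columns `species`, `decimalLatitude`,
#' `decimalLongitude`; optional `depth` (m) and `month` (1-12). Rows with
#' missing or out-of-range coordinates are dropped and counted; longitudes
#' are normalised to \[-180, 180).
#'
#' @param path CSV file path.
#' @return Data frame of validated records; drop counts in the
#'   `"drop_counts"` attribute.
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("species", "decimalLatitude", "decimalLongitude")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("missing required column(s) ", paste(missing_cols, collapse = ", "),
         "; found: ", paste(names(df), collapse = ", "))
  n0 <- nrow(df)
  lat <- suppressWarnings(as.numeric(df$decimalLatitude))
  lon <- suppressWarnings(as.numeric(df$decimalLongitude))
  ok <- is.finite(lat) & is.finite(lon) & lat >= -90 & lat <= 90
  df <- df[ok, , drop = FALSE]
  df$decimalLatitude <- lat[ok]
  df$decimalLongitude <- ((lon[ok] + 180) %% 360) - 180
  if (!"depth" %in% names(df)) df$depth <- NA_real_
  if (!"month" %in% names(df)) df$month <- NA_integer_
  bad_month <- !is.na(df$month) & !(df$month %in% 1:12)
  df$month[bad_month] <- NA_integer_
  rownames(df) <- NULL
  attr(df, "drop_counts") <- list(read = n0, dropped_coords = n0 - nrow(df),
                                  month_invalid = sum(bad_month))
  df
}

#' Write occurrence records to CSV
#'
#' @param occurrences Data frame of records.
#' @param path Output CSV path.
#' @export
write_occurrences <- function(occurrences, path) {
  utils::write.csv(occurrences, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# full-precision text rendering of doubles (round-trips exactly)
.fmt_num <- function(x) sprintf("%.17g", x)

#' Write / read an environment grid in the bundled plain-text format
#'
#' The format is a directory holding `grid.json` (axes and metadata, full
#' numeric precision) and `fields.csv` (flattened `T`, `pO2`, `volume`,
#' `mask` columns in array order, doubles rendered with 17 significant
#' digits). Writing then reading reproduces the grid bit for bit.
#'
#' @param env An `env_grid`.
#' @param path Target directory (created if needed).
#' @return `write_env_grid`: the path, invisibly. `read_env_grid`: an
#'   `env_grid`.
#' @export
write_env_grid <- function(env, path) {
  stopifnot(inherits(env, "env_grid"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(format = "aerotraits-grid", version = 1L,
               lon = env$lon, lat = env$lat, depth = env$depth,
               month = env$month, resolution_deg = env$resolution_deg,
               depth_bounds = env$depth_bounds, seed = env$seed,
               dim_T = dim(env$T))
  jsonlite::write_json(meta, file.path(path, "grid.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  nmon <- dim(env$T)[4]
  vol_rep <- rep(as.vector(env$volume), times = nmon)
  msk_rep <- rep(as.integer(env$mask), times = nmon)
  lines <- c("T,pO2,volume,mask",
             paste(.fmt_num(as.vector(env$T)), .fmt_num(as.vector(env$pO2)),
                   .fmt_num(vol_rep), msk_rep, sep = ","))
  writeLines(lines, file.path(path, "fields.csv"))
  invisible(path)
}

#' @rdname write_env_grid
#' @export
read_env_grid <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "grid.json"),
                              simplifyVector = TRUE)
  if (is.null(meta$format) || meta$format != "aerotraits-grid")
    stop("not an aerotraits grid directory: ", path)
  f <- utils::read.csv(file.path(path, "fields.csv"),
                       colClasses = c("numeric", "numeric",
                                      "character", "character"))
  dT <- as.integer(meta$dim_T)
  n3 <- prod(dT[1:3])
  vol <- as.numeric(f$volume[seq_len(n3)])
  msk <- as.integer(f$mask[seq_len(n3)]) == 1L
  structure(
    list(lon = as.numeric(meta$lon), lat = as.numeric(meta$lat),
         depth = as.numeric(meta$depth),
         month = if (length(meta$month) > 1) as.integer(meta$month)
                 else NA_integer_,
         T = array(f$T, dim = dT), pO2 = array(f$pO2, dim = dT),
         volume = array(vol, dim = dT[1:3]),
         mask = array(msk, dim = dT[1:3]),
         resolution_deg = as.numeric(meta$resolution_deg),
         depth_bounds = as.numeric(meta$depth_bounds),
         seed = meta$seed, params = NULL),
    class = "env_grid")
}

#' Environment-grid reader with unit handling
#'
#' Reads the bundled plain-text grid format. Temperature declared in Kelvin
#' is converted to degC; O2 given as concentration (umol/kg) is routed
#' through [o2conc_to_po2()]. No silent unit coercion: conversions are
#' reported with a message.
#'
#' @param path Grid directory (see [write_env_grid()]).
#' @param temperature_units `"degC"` (default) or `"K"`.
#' @param o2_units `"atm"` (default) or `"umol_kg"`.
#' @param salinity Salinity used for concentration conversion.
#' @return An `env_grid`.
#' @export
read_environment <- function(path, temperature_units = c("degC", "K"),
                             o2_units = c("atm", "umol_kg"),
                             salinity = 35) {
  temperature_units <- match.arg(temperature_units)
  o2_units <- match.arg(o2_units)
  env <- read_env_grid(path)
  if (temperature_units == "K") {
    message("converting temperature from K to degC")
    env$T <- env$T - 273.15
  }
  if (o2_units == "umol_kg") {
    message("converting O2 from umol/kg to atm via solubility")
    env$pO2 <- array(o2conc_to_po2(as.vector(env$pO2), as.vector(env$T),
                                   S = salinity),
                     dim = dim(env$pO2))
  }
  env
}

#' Write / read the per-species trait table
#'
#' @param trait_table Data frame from [fit_species_table()].
#' @param path CSV path.
#' @export
write_trait_table <- function(trait_table, path) {
  utils::write.csv(trait_table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trait_table
#' @export
read_trait_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a machine-readable run manifest
#'
#' Records the configuration, seeds, package version and row counts of a
#' pipeline run, plus a hash of the configuration, so identical manifests
#' identify reproducible runs.
#'
#' @param path JSON output path.
#' @param config Named list of configuration values.
#' @param counts Named list of record counts.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, config, counts = list()) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    schema_version = 1L,
    package = "aerotraits",
    package_version = as.character(utils::packageVersion("aerotraits")),
    config = config,
    config_hash = unname(substr(tools::md5sum(
      files = {tf <- tempfile(); writeLines(cfg_json, tf); tf}), 1, 32)),
    counts = counts)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
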