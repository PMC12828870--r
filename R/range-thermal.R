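#' Grid occurrence records onto a quarter-degree presence grid
#'
#' Each record falls in the half-open cell
#' `[floor(coord / resolution) * resolution, + resolution)`; any number
#' of records in a cell collapses to a single presence.
#'
#' @param records Data frame with columns `lat` and `lon` (degrees;
#'   lat in `[-90, 90]`, lon in `[-180, 180)`).
#' @param resolution Cell size in degrees (default 0.25).
#' @return An object of class `kelp_presence_grid`: a data frame with one
#'   row per presence cell (`lat_index`, `lon_index`, `lat0`, `lon0`, the
#'   cell's lower-left corner, and `n_records`), with the resolution in
#'   attribute `resolution`.
#' @export
grid_occurrences <- function(records, resolution = 0.25) {
  stopifnot(is.data.frame(records), all(c("lat", "lon") %in% names(records)))
  bad <- which(!is.finite(records$lat) | !is.finite(records$lon) |
                 records$lat < -90 | records$lat > 90 |
                 records$lon < -180 | records$lon >= 180)
  if (length(bad))
    stop("invalid coordinates in rows: ", paste(bad, collapse = ", "))
  li <- floor(records$lat / resolution)
  lj <- floor(records$lon / resolution)
  if (nrow(records) == 0) {
    grid <- data.frame(lat_index = integer(0), lon_index = integer(0),
                       lat0 = numeric(0), lon0 = numeric(0),
                       n_records = integer(0))
  } else {
    key <- paste(li, lj)
    first <- !duplicated(key)
    counts <- table(key)
    grid <- data.frame(lat_index = li[first], lon_index = lj[first],
                       lat0 = li[first] * resolution,
                       lon0 = lj[first] * resolution,
                       n_records = as.integer(counts[key[first]]))
    grid <- grid[order(grid$lat_index, grid$lon_index), , drop = FALSE]
    rownames(grid) <- NULL
  }
  structure(grid, resolution = resolution,
            class = c("kelp_presence_grid", "data.frame"))
}

#' Attach per-cell climatological mean SST to a presence grid
#'
#' Indexes the climatology field onto the same grid and joins it to the
#' presence cells. Presence cells with no matching field cell (e.g. land-
#' masked) are dropped with a logged count; it is an error when no cell
#' matches.
#'
#' @param grid A [grid_occurrences()] result.
#' @param clim_field Data frame with columns `lat`, `lon` (a point inside
#'   each field cell) and `clim_sst_c` (climatological mean SST, deg C).
#' @return The grid with a `clim_sst_c` column, attribute `n_unmatched`
#'   counting dropped presence cells.
#' @export
attach_cell_climatology <- function(grid, clim_field) {
  stopifnot(inherits(grid, "kelp_presence_grid"),
            all(c("lat", "lon", "clim_sst_c") %in% names(clim_field)))
  res <- attr(grid, "resolution")
  fkey <- paste(floor(clim_field$lat / res), floor(clim_field$lon / res))
  gkey <- paste(grid$lat_index, grid$lon_index)
  idx <- match(gkey, fkey)
  n_unmatched <- sum(is.na(idx))
  if (nrow(grid) > 0 && n_unmatched == nrow(grid))
    stop("no presence cell matches the climatology field")
  out <- grid[!is.na(idx), , drop = FALSE]
  out$clim_sst_c <- clim_field$clim_sst_c[idx[!is.na(idx)]]
  if (n_unmatched > 0)
    message(n_unmatched, " presence cell(s) without climatology dropped")
  structure(out, resolution = res, n_unmatched = n_unmatched,
            class = c("kelp_presence_grid", "data.frame"))
}

#' Realised thermal range of a gridded distribution
#'
#' Summarises the climatological mean SST across presence cells. The
#' maximum — the warmest climatology at which the species is found — is
#' the realised proxy for its critical thermal maximum.
#'
#' @param grid A presence grid carrying `clim_sst_c` (see
#'   [attach_cell_climatology()]).
#' @return List with `clim_values`, `min_clim`, `max_clim`,
#'   `realised_ctmax_proxy` (= `max_clim`), `n_cells`.
#' @export
realised_thermal_range <- function(grid) {
  stopifnot(inherits(grid, "kelp_presence_grid"))
  if (!"clim_sst_c" %in% names(grid) || nrow(grid) == 0)
    stop("presence grid has no climatology-bearing cells")
  v <- grid$clim_sst_c
  list(clim_values = v, min_clim = min(v), max_clim = max(v),
       realised_ctmax_proxy = max(v), n_cells = length(v))
}

#' Thermal safety margin
#'
#' The buffer between a population's upper thermal limit and the
#' climatological temperature it experiences; negative margins mean the
#' experienced climate already exceeds the limit.
#'
#' @param upper_limit Upper thermal limit (deg C), e.g. a fitted or
#'   realised CTmax.
#' @param experienced_clim Experienced climatological SST (deg C).
#' @return `upper_limit - experienced_clim` (deg C), vectorised.
#' @export
thermal_safety_margin <- function(upper_limit, experienced_clim) {
  stopifnot(all(is.finite(upper_limit)), all(is.finite(experienced_clim)))
  upper_limit - experienced_clim
}
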