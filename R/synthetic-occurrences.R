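#' Generate synthetic occurrence records
#'
#' Scatters presence records over a latitude/longitude box. With
#' `clustering > 1`, records are grouped into hotspots of that many
#' records each, jittered tightly around a shared centre so that several
#' records fall in one quarter-degree cell — exercising downstream
#' deduplication.
#'
#' @param n_records Number of records (>= 0).
#' @param lat_range,lon_range Length-2 numeric bounds of the box
#'   (degrees); must be non-degenerate.
#' @param clustering Records per hotspot (default 1 = uniform scatter).
#' @param jitter_sd SD of the within-hotspot jitter (degrees).
#' @param seed Integer seed.
#' @return Data frame with columns `lat`, `lon`.
#' @export
generate_occurrences <- function(n_records, lat_range, lon_range,
                                 clustering = 1, jitter_sd = 0.02,
                                 seed = 1L) {
  stopifnot(is_scalar_number(n_records), n_records >= 0,
            length(lat_range) == 2L, length(lon_range) == 2L)
  if (diff(lat_range) <= 0 || diff(lon_range) <= 0)
    stop("lat/lon box must be non-degenerate")
  n_records <- as.integer(n_records)
  if (n_records == 0L)
    return(data.frame(lat = numeric(0), lon = numeric(0)))
  withr::with_seed(as.integer(seed), {
    if (clustering <= 1) {
      lat <- stats::runif(n_records, lat_range[1], lat_range[2])
      lon <- stats::runif(n_records, lon_range[1], lon_range[2])
    } else {
      n_hot <- ceiling(n_records / clustering)
      c_lat <- stats::runif(n_hot, lat_range[1], lat_range[2])
      c_lon <- stats::runif(n_hot, lon_range[1], lon_range[2])
      idx <- rep(seq_len(n_hot), each = clustering)[seq_len(n_records)]
      lat <- c_lat[idx] + stats::rnorm(n_records, 0, jitter_sd)
      lon <- c_lon[idx] + stats::rnorm(n_records, 0, jitter_sd)
      lat <- pmin(pmax(lat, lat_range[1]), lat_range[2])
      lon <- pmin(pmax(lon, lon_range[1]), lon_range[2])
    }
    data.frame(lat = lat, lon = lon)
  })
}
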