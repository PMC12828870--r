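# Plain-text interchange: CSV readers/writers for every pipeline stage.

#' Read a daily SST series from CSV
#'
#' Expects columns `date` (ISO-8601) and `sst_c`.
#'
#' @param path CSV file path.
#' @param location_id Optional label attached to the series.
#' @return Validated SST data frame (`date`, `sst_c`).
#' @export
read_sst_csv <- function(path, location_id = NULL) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- validate_sst_series(x[, c("date", "sst_c")])
  attr(out, "location_id") <- location_id
  out
}

#' Write a daily SST series to CSV
#' @param series SST data frame (`date`, `sst_c`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sst_csv <- function(series, path) {
  utils::write.csv(series[, c("date", "sst_c")], path, row.names = FALSE)
  invisible(path)
}

#' Read survey records from CSV
#'
#' Expects columns `location`, `site`, `date` (ISO-8601), `cover_pct`;
#' an optional logical `clipped` column is kept.
#'
#' @param path CSV file path.
#' @return Survey data frame with `date` parsed as Date.
#' @export
read_surveys_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("location", "site", "date", "cover_pct") %in% names(x)))
  x$date <- as.Date(x$date)
  if (any(x$cover_pct < 0 | x$cover_pct > 100))
    stop("cover_pct outside [0, 100]")
  x
}

#' Write survey records to CSV
#' @param surveys Survey data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_surveys_csv <- function(surveys, path) {
  utils::write.csv(surveys, path, row.names = FALSE)
  invisible(path)
}

#' Read occurrence records from CSV
#'
#' Expects columns `lat` and `lon`; an optional `date` column is kept.
#'
#' @param path CSV file path.
#' @return Occurrence data frame.
#' @export
read_occurrences_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("lat", "lon") %in% names(x)))
  x
}

#' Write occurrence records to CSV
#' @param records Occurrence data frame (`lat`, `lon`, optional `date`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_occurrences_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}
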