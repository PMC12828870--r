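# Internal calendar helpers. Daily SST uses the real (leap-aware) calendar;
# climatologies use a fixed 365-slot year in which Feb 29 shares Feb 28's slot.

#' @noRd
doy365 <- function(dates) {
  lt <- as.POSIXlt(dates)
  m <- lt$mon + 1L
  d <- lt$mday
  d[m == 2L & d == 29L] <- 28L
  cum <- c(0L, cumsum(c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L)))
  cum[m] + d
}

#' @noRd
date_year <- function(dates) as.POSIXlt(dates)$year + 1900L

#' @noRd
date_month <- function(dates) as.POSIXlt(dates)$mon + 1L

# Warm season of `season_year` runs 1 Dec (season_year - 1) .. 30 Apr.
#' @noRd
season_start <- function(season_year) as.Date(sprintf("%d-12-01", season_year - 1L))

#' @noRd
season_end <- function(season_year) as.Date(sprintf("%d-04-30", season_year))

#' @noRd
is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# memo for deterministic warm-season anchors
.anchor_cache <- new.env(parent = emptyenv())
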