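#' Filter survey records by location-specific month rules
#'
#' Restricts each location's surveys to an allowed set of calendar months,
#' as when a location surveyed in varying months is limited to its
#' highest-frequency season. Locations without a rule (or with an empty
#' rule) keep all records.
#'
#' @param surveys Data frame with at least `location` and `date`.
#' @param rules Named list mapping location to an integer vector of
#'   allowed months, e.g. `list(maria_island = 3:5)`.
#' @return The filtered data frame.
#' @export
filter_survey_months <- function(surveys, rules = list()) {
  if (nrow(surveys) == 0 || length(rules) == 0) return(surveys)
  mon <- date_month(as.Date(surveys$date))
  keep <- rep(TRUE, nrow(surveys))
  for (loc in names(rules)) {
    allowed <- rules[[loc]]
    if (length(allowed) == 0) next
    sel <- surveys$location == loc
    keep[sel] <- mon[sel] %in% allowed
  }
  surveys[keep, , drop = FALSE]
}

#' Pair consecutive surveys into per-summer cover changes
#'
#' For each site, consecutive surveys are paired when their gap does not
#' exceed `max_gap_years` and at least one warm season's January lies
#' wholly inside the interval `(date_before, date_after]`. The attached
#' season is the latest such January's year; when more than one season
#' lies between the surveys the pair is flagged `multi_season`, and
#' `season_complete` records whether the season's 30 April falls on or
#' before the second survey. Same-site surveys within one calendar day
#' are averaged first. Unpairable surveys are dropped with a logged count.
#'
#' @param surveys Data frame with `location`, `site`, `date`, `cover_pct`
#'   and optionally `clipped`.
#' @param max_gap_years Maximum survey gap in years (default 2).
#' @return Data frame of cover-change pairs: `location`, `site`,
#'   `date_before`, `date_after`, `cover_before`, `cover_after`,
#'   `delta_cover`, `season_year`, `multi_season`, `season_complete`,
#'   `clipped` (TRUE when the arriving survey's cover was clipped);
#'   attribute `n_dropped` counts pairs discarded by the gap or season
#'   rules.
#' @export
pair_consecutive_surveys <- function(surveys, max_gap_years = 2) {
  cols <- c("location", "site", "date", "cover_pct")
  stopifnot(all(cols %in% names(surveys)))
  surveys$date <- as.Date(surveys$date)
  if (!"clipped" %in% names(surveys)) surveys$clipped <- FALSE
  # average same-day replicates per site
  key <- interaction(surveys$location, surveys$site, surveys$date, drop = TRUE)
  agg <- data.frame(
    location = tapply(surveys$location, key, `[`, 1),
    site = tapply(surveys$site, key, `[`, 1),
    date = as.Date(as.numeric(tapply(surveys$date, key, `[`, 1)),
                   origin = "1970-01-01"),
    cover_pct = as.numeric(tapply(surveys$cover_pct, key, mean)),
    clipped = as.logical(tapply(surveys$clipped, key, any)),
    row.names = NULL)
  agg <- agg[order(agg$location, agg$site, agg$date), , drop = FALSE]
  # per-year calendar marks, precomputed once
  yr_all <- date_year(agg$date)
  yrs <- if (nrow(agg)) seq(min(yr_all), max(yr_all) + 1L) else integer(0)
  jan1 <- as.numeric(as.Date(sprintf("%d-01-01", yrs)))
  jan31 <- as.numeric(as.Date(sprintf("%d-01-31", yrs)))
  apr30 <- as.numeric(as.Date(sprintf("%d-04-30", yrs)))
  n_dropped <- 0L
  pairs <- list()
  for (grp in split(agg, interaction(agg$location, agg$site, drop = TRUE))) {
    if (nrow(grp) < 2) next
    dn <- as.numeric(grp$date)
    # calendar-exact gap bound: same month/day max_gap_years later qualifies
    gap_limit <- {
      lt <- as.POSIXlt(grp$date)
      lt$year <- lt$year + as.integer(max_gap_years)
      as.numeric(as.Date(lt))
    }
    for (i in seq_len(nrow(grp) - 1)) {
      if (dn[i + 1] > gap_limit[i]) {
        n_dropped <- n_dropped + 1L
        next
      }
      inside <- jan1 > dn[i] & jan31 <= dn[i + 1]
      if (!any(inside)) {
        n_dropped <- n_dropped + 1L
        next
      }
      season_idx <- max(which(inside))
      pairs[[length(pairs) + 1L]] <- list(
        location = grp$location[i], site = grp$site[i],
        date_before = grp$date[i], date_after = grp$date[i + 1],
        cover_before = grp$cover_pct[i], cover_after = grp$cover_pct[i + 1],
        delta_cover = grp$cover_pct[i + 1] - grp$cover_pct[i],
        season_year = yrs[season_idx],
        multi_season = sum(inside) > 1L,
        season_complete = apr30[season_idx] <= dn[i + 1],
        clipped = grp$clipped[i + 1])
    }
  }
  out <- if (length(pairs)) {
    data.frame(
      location = vapply(pairs, `[[`, character(1), "location"),
      site = vapply(pairs, `[[`, character(1), "site"),
      date_before = as.Date(vapply(pairs, function(p)
        as.numeric(p$date_before), numeric(1)), origin = "1970-01-01"),
      date_after = as.Date(vapply(pairs, function(p)
        as.numeric(p$date_after), numeric(1)), origin = "1970-01-01"),
      cover_before = vapply(pairs, `[[`, numeric(1), "cover_before"),
      cover_after = vapply(pairs, `[[`, numeric(1), "cover_after"),
      delta_cover = vapply(pairs, `[[`, numeric(1), "delta_cover"),
      season_year = vapply(pairs, `[[`, integer(1), "season_year"),
      multi_season = vapply(pairs, `[[`, logical(1), "multi_season"),
      season_complete = vapply(pairs, `[[`, logical(1), "season_complete"),
      clipped = vapply(pairs, `[[`, logical(1), "clipped"))
  } else {
    data.frame(location = character(0), site = character(0),
               date_before = as.Date(character(0)),
               date_after = as.Date(character(0)),
               cover_before = numeric(0), cover_after = numeric(0),
               delta_cover = numeric(0), season_year = integer(0),
               multi_season = logical(0), season_complete = logical(0),
               clipped = logical(0))
  }
  rownames(out) <- NULL
  out <- out[order(out$location, out$site, out$date_before), , drop = FALSE]
  if (n_dropped > 0)
    message(n_dropped, " survey pair(s) dropped (gap or season rule)")
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Attach warm-season metrics to cover-change pairs
#'
#' Joins each pair with the metrics of its intervening warm season,
#' producing the analysis table for the response models.
#'
#' @param pairs Output of [pair_consecutive_surveys()].
#' @param metrics Data frame keyed by `location` and `season_year` with
#'   metric columns, e.g. from [warm_season_metrics_table()].
#' @return One row per pair, carrying all pair and metric columns.
#' @export
attach_metrics <- function(pairs, metrics) {
  stopifnot(all(c("location", "season_year") %in% names(metrics)))
  if (nrow(pairs) == 0) {
    out <- merge(pairs, metrics, by = c("location", "season_year"))
    return(out[, union(names(pairs), names(metrics)), drop = FALSE])
  }
  key_p <- paste(pairs$location, pairs$season_year)
  key_m <- paste(metrics$location, metrics$season_year)
  miss <- unique(key_p[!key_p %in% key_m])
  if (length(miss))
    stop("no warm-season metrics for (location, season): ",
         paste(miss, collapse = ", "))
  idx <- match(key_p, key_m)
  extra <- setdiff(names(metrics), c("location", "season_year"))
  out <- cbind(pairs, metrics[idx, extra, drop = FALSE])
  rownames(out) <- NULL
  out
}
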