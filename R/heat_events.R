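#' Extreme-heat-event definition
#'
#' The two canonical run rules: `EHE95` = at least 2 consecutive days with
#' daily maximum temperature (Tmax) strictly above the 95th percentile of
#' the station's Tmax distribution for the season and year; `EHE90` = at
#' least 3 consecutive days above the 90th percentile. Arbitrary
#' `(q, min_run)` pairs are allowed for exploratory use.
#'
#' @param name `"EHE95"`, `"EHE90"`, or a custom label when `q`/`min_run`
#'   are supplied.
#' @param q percentile (0-100); defaults from `name`.
#' @param min_run minimum run length in days; defaults from `name`.
#' @return object of class `ehe_definition`: list with `name`, `q`,
#'   `min_run`.
#' @export
ehe_definition <- function(name = c("EHE95", "EHE90"), q = NULL,
                           min_run = NULL) {
  if (is.null(q) && is.null(min_run)) {
    name <- match.arg(name)
    q <- if (name == "EHE95") 95 else 90
    min_run <- if (name == "EHE95") 2L else 3L
  } else {
    if (is.null(q) || is.null(min_run)) {
      stop("supply both q and min_run for a custom definition", call. = FALSE)
    }
    name <- as.character(name[1])
  }
  stopifnot(q > 0, q < 100, min_run >= 1)
  structure(list(name = name, q = q, min_run = as.integer(min_run)),
            class = "ehe_definition")
}

# Calendar span of a season-year block (winter `year` = Dec year-1 .. Feb
# year; fixed for determinism even though winter never enters the
# spring/summer analyses).
.season_span <- function(season, year) {
  switch(season,
    spring = c(as.Date(sprintf("%d-03-01", year)),
               as.Date(sprintf("%d-05-31", year))),
    summer = c(as.Date(sprintf("%d-06-01", year)),
               as.Date(sprintf("%d-08-31", year))),
    autumn = c(as.Date(sprintf("%d-09-01", year)),
               as.Date(sprintf("%d-11-30", year))),
    winter = c(as.Date(sprintf("%d-12-01", year - 1)),
               as.Date(sprintf("%d-02-01", year)) + 27 +
                 as.integer(lubridate::leap_year(year))),
    stop("unknown season: ", season, call. = FALSE)
  )
}

#' Season-and-year-specific Tmax percentile threshold
#'
#' Linear-interpolation percentile (same type-7 convention as the PM2.5
#' cut-point) of a station's non-missing Tmax values within one season-year.
#'
#' @param series daily series for one station (`date`, `tmax`).
#' @param season one of `"spring"`, `"summer"`, `"autumn"`, `"winter"`.
#' @param year season-year (December counts toward the following winter).
#' @param q percentile, 0-100.
#' @param min_obs minimum non-missing days required; below it the threshold
#'   is undefined (NA, with a warning) and the season-year is skipped.
#' @return threshold in degrees C, or NA.
#' @export
seasonal_threshold <- function(series, season, year, q, min_obs = 10L) {
  sel <- season_of(series$date) == season & season_year(series$date) == year &
    !is.na(series$tmax)
  vals <- series$tmax[sel]
  if (length(vals) < min_obs) {
    warning(sprintf("threshold undefined: only %d Tmax day(s) in %s %d",
                    length(vals), season, year), call. = FALSE)
    return(NA_real_)
  }
  .pctl(vals, q / 100)
}

# Maximal qualifying runs over one contiguous day grid. `above` is logical
# with NA treated as FALSE (missing days break runs).
.runs <- function(above, min_run) {
  above[is.na(above)] <- FALSE
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  cbind(start = starts[keep], end = ends[keep])
}

#' Detect extreme heat events
#'
#' Scans each station-season-year segment independently (the threshold is
#' defined per season and year, and runs never cross season boundaries) for
#' maximal runs of consecutive calendar days with Tmax strictly above the
#' segment's threshold; runs of at least `min_run` days become events.
#' Missing Tmax days and days exactly at the threshold break runs.
#'
#' @param series daily weather tibble; may contain several stations
#'   (`station_id` column), each scanned separately.
#' @param definition an [ehe_definition()].
#' @param thresholds optional override for exploratory/testing use: a single
#'   number applied everywhere, or a data frame `(season, year, threshold)`.
#'   By default thresholds are computed from the data with
#'   [seasonal_threshold()].
#' @param min_obs passed to [seasonal_threshold()].
#' @return tibble of events: `station_id`, `start`, `end` (inclusive),
#'   `n_days`, `definition`, `season`, `year`, `threshold`; zero rows when
#'   no event qualifies.
#' @export
detect_events <- function(series, definition, thresholds = NULL,
                          min_obs = 10L) {
  stopifnot(inherits(definition, "ehe_definition"))
  if (!"station_id" %in% names(series)) series$station_id <- "station"
  empty <- tibble::tibble(station_id = character(), start = as.Date(character()),
                          end = as.Date(character()), n_days = integer(),
                          definition = character(), season = character(),
                          year = integer(), threshold = numeric())
  out <- list()
  for (sid in unique(series$station_id)) {
    ser <- series[series$station_id == sid, , drop = FALSE]
    rng <- range(ser$date)
    seg <- unique(data.frame(season = season_of(ser$date),
                             year = season_year(ser$date)))
    for (k in seq_len(nrow(seg))) {
      season <- seg$season[k]; year <- seg$year[k]
      thr <- if (is.null(thresholds)) {
        seasonal_threshold(ser, season, year, definition$q, min_obs)
      } else if (is.data.frame(thresholds)) {
        hit <- thresholds$season == season & thresholds$year == year
        if (any(hit)) thresholds$threshold[hit][1] else NA_real_
      } else {
        as.numeric(thresholds)
      }
      if (is.na(thr)) next
      span <- .season_span(season, year)
      days <- seq(max(span[1], rng[1]), min(span[2], rng[2]), by = "day")
      tmax <- ser$tmax[match(days, ser$date)]
      runs <- .runs(!is.na(tmax) & tmax > thr, definition$min_run)
      if (nrow(runs) == 0) next
      out[[length(out) + 1]] <- tibble::tibble(
        station_id = sid, start = days[runs[, "start"]],
        end = days[runs[, "end"]],
        n_days = runs[, "end"] - runs[, "start"] + 1L,
        definition = definition$name, season = season, year = year,
        threshold = thr)
    }
  }
  if (length(out) == 0) return(empty)
  res <- dplyr::bind_rows(out)
  res[order(res$station_id, res$start), , drop = FALSE]
}

#' Was a pregnancy window exposed to an extreme heat event?
#'
#' Any-overlap rule: exposed if at least one day of any qualifying event
#' falls inside the inclusive window, since the heat is experienced on each
#' event day regardless of where the event starts or ends.
#'
#' @param start,end inclusive window bounds (single window).
#' @param events event tibble from [detect_events()] for the subject's
#'   linked station.
#' @return logical scalar.
#' @export
window_ehe_exposure <- function(start, end, events) {
  if (nrow(events) == 0) return(FALSE)
  any(events$start <= as.Date(end) & events$end >= as.Date(start))
}
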