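#' Estimate the conception date from the estimated date of delivery
#'
#' Uses the standard clinical convention of a 266-day (38 postconceptional
#' weeks) term: `conception = edd - 266`. For reconstruction from an actual
#' delivery date and gestational age instead, see
#' [conception_from_delivery()].
#'
#' @param edd estimated date(s) of delivery (`Date` or ISO-8601 string).
#' @return `Date` vector of estimated conception dates.
#' @export
conception_date <- function(edd) {
  edd <- as.Date(edd)
  if (anyNA(edd)) stop("invalid edd", call. = FALSE)
  edd - 266L
}

#' Reconstruct the conception date from delivery date and gestational age
#'
#' Alternative mode for users whose data carry the delivery date and a
#' gestational age in completed (menstrual) weeks: conception is taken as
#' two weeks after the start of gestational ageing,
#' `delivery - 7 * gestational_age_weeks + 14`.
#'
#' @param delivery_date delivery date(s).
#' @param gestational_age_weeks gestational age at delivery, weeks.
#' @return `Date` vector of estimated conception dates.
#' @export
conception_from_delivery <- function(delivery_date, gestational_age_weeks) {
  delivery_date <- as.Date(delivery_date)
  if (anyNA(delivery_date)) stop("invalid delivery_date", call. = FALSE)
  delivery_date - 7L * as.integer(gestational_age_weeks) + 14L
}

#' Critical window for cardiogenesis (postconceptional weeks 3-8)
#'
#' Postconceptional day 1 is the first day after conception; week k covers
#' days `7(k-1)+1 .. 7k`, so weeks 3-8 are days 15-56: a 42-day window
#' running from `conception + 14` through `conception + 55`, both inclusive.
#'
#' @param conception conception date(s).
#' @return tibble with columns `conception`, `start`, `end` (inclusive).
#' @export
critical_window <- function(conception) {
  conception <- as.Date(conception)
  if (anyNA(conception)) stop("invalid conception date", call. = FALSE)
  tibble::tibble(conception = conception,
                 start = conception + 14L,
                 end = conception + 55L)
}

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371 km.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (vectorized).
#' @return numeric vector of distances, km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90, na.rm = TRUE) ||
      any(abs(c(lon1, lon2)) > 180, na.rm = TRUE)) {
    stop("coordinates out of range (|lat| <= 90, |lon| <= 180)", call. = FALSE)
  }
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371)
}

#' Nearest monitoring site to a point
#'
#' Minimum great-circle distance over a site list, optionally subject to a
#' distance cap (the PM2.5 linkage uses 50 km; weather-station linkage is
#' uncapped). Ties in distance are broken by the lexicographically smallest
#' site id so the linkage is deterministic.
#'
#' @param lat,lon subject coordinates, decimal degrees.
#' @param sites data frame with columns `site_id`, `latitude`, `longitude`.
#' @param max_km optional cap; if the nearest site is farther, no site is
#'   assigned.
#' @return one-row tibble `site_id`, `distance_km`; both NA when the cap
#'   excludes every site.
#' @export
nearest_site <- function(lat, lon, sites, max_km = NULL) {
  sites <- as.data.frame(sites)
  if (nrow(sites) == 0) stop("empty site list", call. = FALSE)
  d <- haversine_km(lat, lon, sites$latitude, sites$longitude)
  i <- order(d, as.character(sites$site_id))[1]
  if (!is.null(max_km) && d[i] > max_km) {
    return(tibble::tibble(site_id = NA_character_, distance_km = NA_real_))
  }
  tibble::tibble(site_id = as.character(sites$site_id[i]), distance_km = d[i])
}

#' Mean of a daily series over an exposure window
#'
#' Arithmetic mean of the available in-window daily values; declared missing
#' when fewer than `min_days` days are available.
#'
#' @param dates,values the daily series (missing days simply absent).
#' @param start,end inclusive window bounds.
#' @param min_days minimum number of available days for a defined mean.
#' @return one-row tibble `mean` (NA if coverage is insufficient), `n_days`.
#' @export
window_mean <- function(dates, values, start, end, min_days = 1L) {
  stopifnot(min_days >= 1)
  keep <- !is.na(values) & dates >= as.Date(start) & dates <= as.Date(end)
  n <- sum(keep)
  tibble::tibble(mean = if (n >= min_days) mean(values[keep]) else NA_real_,
                 n_days = n)
}

# Linear-interpolation percentile between order statistics at
# h = (n - 1) p + 1 (quantile type 7). Shared by the PM2.5 cut-point and
# the seasonal Tmax thresholds so all cutoffs are bit-reproducible.
.pctl <- function(x, p) {
  as.numeric(stats::quantile(x, p, type = 7, names = FALSE, na.rm = FALSE))
}

#' Dichotomize window-average PM2.5 at a control percentile
#'
#' The cut-point is the given percentile (default 80th, linear-interpolation
#' convention) of the non-missing window means among controls only, so
#' adding or removing cases never moves the threshold. `pm_high` is strict:
#' a mean exactly at the threshold is classified low.
#'
#' @param exposure exposure table with a `mean_pm25` column.
#' @param is_control logical vector, one per row of `exposure`.
#' @param percentile percentile of the control distribution, default 80.
#' @return `exposure` with `pm_high` set (NA where `mean_pm25` is missing)
#'   and the threshold attached as attribute `pm_threshold`.
#' @export
dichotomize_pm <- function(exposure, is_control, percentile = 80) {
  stopifnot(length(is_control) == nrow(exposure))
  ctrl <- exposure$mean_pm25[is_control & !is.na(exposure$mean_pm25)]
  if (length(ctrl) < 2) {
    stop("need at least 2 controls with non-missing PM2.5 to set the cut-point",
         call. = FALSE)
  }
  thr <- .pctl(ctrl, percentile / 100)
  exposure$pm_high <- exposure$mean_pm25 > thr
  attr(exposure, "pm_threshold") <- thr
  exposure
}

#' Meteorological season of a date
#'
#' Month-based seasons: MAM = spring, JJA = summer, SON = autumn,
#' DJF = winter.
#'
#' @param dates `Date` vector.
#' @return character vector in `{"spring","summer","autumn","winter"}`.
#' @export
season_of <- function(dates) {
  m <- lubridate::month(as.Date(dates))
  c("winter", "winter", "spring", "spring", "spring", "summer", "summer",
    "summer", "autumn", "autumn", "autumn", "winter")[m]
}

#' Season-year of a date
#'
#' The year label of the season a date belongs to; December is assigned to
#' the following January's winter so each DJF block has a single year.
#'
#' @param dates `Date` vector.
#' @return integer vector of season-years.
#' @export
season_year <- function(dates) {
  d <- as.Date(dates)
  as.integer(lubridate::year(d)) + as.integer(lubridate::month(d) == 12)
}

#' Season flags of a critical window
#'
#' The three subpopulation indicators evaluated over every day of the
#' window: at least one day in spring or summer, the entire window within
#' spring/summer, and at least one day in summer.
#'
#' @param start,end inclusive window bounds (vectorized, equal length).
#' @return tibble with logical columns `any_day_spring_summer`,
#'   `entire_window_spring_summer`, `any_day_summer`.
#' @export
season_flags <- function(start, end) {
  start <- as.Date(start)
  end <- as.Date(end)
  stopifnot(length(start) == length(end), all(end >= start))
  n <- length(start)
  any_ss <- logical(n); all_ss <- logical(n); any_su <- logical(n)
  for (i in seq_len(n)) {
    m <- lubridate::month(seq(start[i], end[i], by = "day"))
    any_ss[i] <- any(m %in% 3:8)
    all_ss[i] <- all(m %in% 3:8)
    any_su[i] <- any(m %in% 6:8)
  }
  tibble::tibble(any_day_spring_summer = any_ss,
                 entire_window_spring_summer = all_ss,
                 any_day_summer = any_su)
}

# Vectorized nearest-site linkage: full subject x site distance matrix,
# argmin per subject with the same id tie-break as nearest_site().
.nearest_many <- function(lat, lon, sites, max_km = NULL) {
  D <- geosphere::distm(cbind(lon, lat),
                        cbind(sites$longitude, sites$latitude),
                        fun = geosphere::distHaversine) / 1000 * (6371 / 6378.137)
  ord <- order(as.character(sites$site_id))
  D <- D[, ord, drop = FALSE]
  ids <- as.character(sites$site_id)[ord]
  best <- max.col(-D, ties.method = "first")
  d <- D[cbind(seq_along(best), best)]
  id <- ids[best]
  if (!is.null(max_km)) {
    out <- d > max_km
    id[out] <- NA_character_
    d[out] <- NA_real_
  }
  tibble::tibble(site_id = id, distance_km = d)
}

# Window means for many subjects against a daily series table, by expanding
# each 42-day window and joining on (site id, date).
.window_means <- function(link, series, id_col, value_col, min_days) {
  ok <- !is.na(link$site_id)
  if (!any(ok)) {
    return(tibble::tibble(subject_id = link$subject_id,
                          mean = NA_real_, n_days = NA_integer_))
  }
  sub <- link[ok, , drop = FALSE]
  wlen <- 42L
  expand <- tibble::tibble(
    subject_id = rep(sub$subject_id, each = wlen),
    site_id = rep(sub$site_id, each = wlen),
    date = rep(sub$start, each = wlen) + rep.int(0:(wlen - 1L), nrow(sub))
  )
  ser <- series[, c(id_col, "date", value_col)]
  names(ser) <- c("site_id", "date", "value")
  ser$site_id <- as.character(ser$site_id)
  joined <- dplyr::inner_join(expand, ser, by = c("site_id", "date"))
  agg <- dplyr::summarise(dplyr::group_by(joined, subject_id),
                          mean = mean(value, na.rm = TRUE),
                          n_days = sum(!is.na(value)), .groups = "drop")
  out <- dplyr::left_join(tibble::tibble(subject_id = link$subject_id),
                          agg, by = "subject_id")
  out$n_days[is.na(out$n_days) & ok] <- 0L
  out$mean[is.na(out$n_days) | out$n_days < min_days] <- NA_real_
  out
}

#' Build the per-subject exposure table
#'
#' Runs the full exposure-assignment chain: conception date and the weeks
#' 3-8 critical window, nearest PM2.5 monitor within `max_monitor_km`,
#' window-average PM2.5 (missing below `min_days` coverage), nearest weather
#' station (uncapped) with window-average dew point, extreme-heat-event
#' exposure flags under each supplied definition, season flags, and the
#' control-percentile PM dichotomization.
#'
#' @param subjects subject tibble (needs `subject_id`, `latitude`,
#'   `longitude`, `edd`; `is_case` only when `dichotomize = "controls"`).
#' @param weather daily weather tibble ([generate_weather()] layout).
#' @param monitors daily PM2.5 tibble ([generate_monitors()] layout).
#' @param min_days minimum in-window days for a defined mean (default 28 of
#'   42, two-thirds coverage; applied to PM2.5 and dew point).
#' @param pm_percentile control percentile for the PM cut (default 80).
#' @param max_monitor_km monitor linkage cap, km (default 50).
#' @param ehe_definitions list of [ehe_definition()]s to flag.
#' @param dichotomize `"controls"` (the study definition; requires
#'   `is_case`), `"all"` (cut at the percentile of the whole table, used
#'   when generating outcomes before case status exists), or `"none"`.
#' @return tibble with one row per subject: window dates, linkage ids and
#'   distances, `n_pm_days`, `mean_pm25`, `pm_high`, `mean_dew_point`, one
#'   `<def>_exposed` flag per definition, season flags and an
#'   `exclusion_reason` (`"no_monitor_within_50km"`,
#'   `"insufficient_pm_days"`, or NA). The PM threshold (if computed) is
#'   attached as attribute `pm_threshold`.
#' @export
build_exposure_table <- function(subjects, weather, monitors,
                                 min_days = 28L, pm_percentile = 80,
                                 max_monitor_km = 50,
                                 ehe_definitions = list(ehe_definition("EHE95"),
                                                        ehe_definition("EHE90")),
                                 dichotomize = c("controls", "all", "none")) {
  dichotomize <- match.arg(dichotomize)
  win <- critical_window(conception_date(subjects$edd))

  mon_sites <- unique(tibble::tibble(site_id = as.character(monitors$monitor_id),
                                     latitude = monitors$latitude,
                                     longitude = monitors$longitude))
  sta_sites <- unique(tibble::tibble(site_id = as.character(weather$station_id),
                                     latitude = weather$latitude,
                                     longitude = weather$longitude))

  n <- nrow(subjects)
  mon_link <- .nearest_many(subjects$latitude, subjects$longitude,
                            mon_sites, max_km = max_monitor_km)
  sta_link <- .nearest_many(subjects$latitude, subjects$longitude, sta_sites)

  pm_link <- tibble::tibble(subject_id = subjects$subject_id,
                            site_id = mon_link$site_id, start = win$start)
  pm_means <- .window_means(pm_link, monitors, "monitor_id", "pm25", min_days)
  dp_link <- tibble::tibble(subject_id = subjects$subject_id,
                            site_id = sta_link$site_id, start = win$start)
  dp_means <- .window_means(dp_link, weather, "station_id", "dew_point",
                            min_days)

  # heat events once per station x definition, then overlap with each window
  ehe_flags <- lapply(ehe_definitions, function(def) {
    events <- detect_events(weather, def)
    flag <- logical(n)
    for (sid in unique(sta_link$site_id)) {
      ev <- events[events$station_id == sid, , drop = FALSE]
      idx <- which(sta_link$site_id == sid)
      if (nrow(ev) == 0 || length(idx) == 0) next
      # any event day inside the window: start_e <= end_w & end_e >= start_w
      flag[idx] <- colSums(
        outer(ev$start, win$end[idx], `<=`) &
          outer(ev$end, win$start[idx], `>=`)) > 0
    }
    flag
  })
  names(ehe_flags) <- vapply(ehe_definitions,
                             function(d) paste0(tolower(d$name), "_exposed"),
                             character(1))

  out <- tibble::tibble(
    subject_id = subjects$subject_id,
    conception = win$conception,
    window_start = win$start,
    window_end = win$end,
    monitor_id = mon_link$site_id,
    monitor_distance_km = mon_link$distance_km,
    n_pm_days = pm_means$n_days,
    mean_pm25 = pm_means$mean,
    pm_high = NA,
    station_id = sta_link$site_id,
    station_distance_km = sta_link$distance_km,
    mean_dew_point = dp_means$mean
  )
  for (nm in names(ehe_flags)) out[[nm]] <- ehe_flags[[nm]]
  out <- dplyr::bind_cols(out, season_flags(win$start, win$end))
  out$exclusion_reason <- dplyr::case_when(
    is.na(out$monitor_id) ~ sprintf("no_monitor_within_%gkm", max_monitor_km),
    is.na(out$mean_pm25) ~ "insufficient_pm_days",
    TRUE ~ NA_character_
  )

  if (dichotomize == "controls") {
    if (!"is_case" %in% names(subjects)) {
      stop('dichotomize = "controls" requires subjects$is_case', call. = FALSE)
    }
    # rows with unknown status (e.g. linkage-excluded) are simply not controls
    out <- dichotomize_pm(out, subjects$is_case %in% FALSE, pm_percentile)
  } else if (dichotomize == "all") {
    out <- dichotomize_pm(out, rep(TRUE, n), pm_percentile)
  }
  out
}
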