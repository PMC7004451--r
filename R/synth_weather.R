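#' Seasonal mean of daily maximum temperature
#'
#' Single-sinusoid annual cycle used by the weather generator:
#' `base + amplitude * cos(2 * pi * (yday - peak_day) / 365.25)`.
#' The curve attains `base + amplitude` on `peak_day` (day of year) and
#' `base - amplitude` half a year away.
#'
#' @param dates vector of `Date`s.
#' @param base annual mean Tmax, degrees C.
#' @param amplitude half-range of the seasonal cycle, degrees C (>= 0).
#' @param peak_day day of year (1-366) on which the seasonal mean peaks;
#'   the default 196 is mid-July, typical of the continental United States.
#' @return numeric vector of seasonal mean Tmax, degrees C.
#' @export
seasonal_tmax <- function(dates, base = 15, amplitude = 12, peak_day = 196) {
  stopifnot(amplitude >= 0, peak_day >= 1, peak_day <= 366)
  base + amplitude * cos(2 * pi * (lubridate::yday(dates) - peak_day) / 365.25)
}

#' Simulate daily weather-station series
#'
#' Generates one daily record per station per calendar day in
#' `[start_date, end_date]`. Daily maximum temperature is the seasonal
#' sinusoid ([seasonal_tmax()]) plus a stationary AR(1) anomaly, giving the
#' day-to-day persistence that makes multi-day runs above seasonal percentile
#' thresholds (extreme heat events) occur at realistic rates. Dew point is
#' Tmax minus a fixed offset plus independent Gaussian noise, so it tracks
#' warm spells the way atmospheric moisture does.
#'
#' @param stations data frame with columns `station_id`, `latitude`,
#'   `longitude` (decimal degrees).
#' @param start_date,end_date inclusive date range (`Date` or ISO-8601 string).
#' @param base,amplitude,peak_day seasonal-cycle parameters, see
#'   [seasonal_tmax()].
#' @param ar1_rho lag-1 autocorrelation of the Tmax anomaly, `|ar1_rho| < 1`.
#' @param noise_sd innovation standard deviation of the AR(1) anomaly,
#'   degrees C (>= 0). `noise_sd = 0` gives the seasonal curve exactly.
#' @param dewpoint_offset mean Tmax - dew point spread, degrees C.
#' @param dewpoint_noise_sd standard deviation of independent dew-point
#'   noise, degrees C.
#' @param seed optional integer; fixing it makes the output reproducible.
#' @return tibble with columns `station_id`, `latitude`, `longitude`,
#'   `date`, `tmax`, `dew_point`, date-ordered within station.
#' @export
generate_weather <- function(stations, start_date, end_date,
                             base = 15, amplitude = 12, peak_day = 196,
                             ar1_rho = 0.7, noise_sd = 3,
                             dewpoint_offset = 8, dewpoint_noise_sd = 1.5,
                             seed = NULL) {
  stations <- as.data.frame(stations)
  stopifnot(all(c("station_id", "latitude", "longitude") %in% names(stations)),
            nrow(stations) >= 1)
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  if (is.na(start_date) || is.na(end_date) || start_date > end_date) {
    stop("invalid date range: start_date must be <= end_date", call. = FALSE)
  }
  if (!is.finite(ar1_rho) || abs(ar1_rho) >= 1) {
    stop("ar1_rho must satisfy |ar1_rho| < 1 (stationarity)", call. = FALSE)
  }
  stopifnot(noise_sd >= 0, dewpoint_noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)

  dates <- seq(start_date, end_date, by = "day")
  n <- length(dates)
  mu <- seasonal_tmax(dates, base, amplitude, peak_day)

  out <- lapply(seq_len(nrow(stations)), function(i) {
    innov <- stats::rnorm(n, 0, noise_sd)
    if (n > 0 && noise_sd > 0) {
      # stationary start: var(a) = noise_sd^2 / (1 - rho^2)
      innov[1] <- stats::rnorm(1, 0, noise_sd / sqrt(1 - ar1_rho^2))
    }
    anom <- as.numeric(stats::filter(innov, ar1_rho, method = "recursive"))
    tmax <- mu + anom
    dew <- tmax - dewpoint_offset + stats::rnorm(n, 0, dewpoint_noise_sd)
    tibble::tibble(
      station_id = stations$station_id[i],
      latitude = stations$latitude[i],
      longitude = stations$longitude[i],
      date = dates, tmax = tmax, dew_point = dew
    )
  })
  dplyr::bind_rows(out)
}

#' Simulate daily PM2.5 monitor series
#'
#' Daily 24-hour mean PM2.5 concentrations are log-normal about a seasonal
#' mean level, with a configurable fraction of days missing completely at
#' random (monitor outages / sampling schedules).
#'
#' @param monitors data frame with columns `monitor_id`, `latitude`,
#'   `longitude`.
#' @param start_date,end_date inclusive date range.
#' @param mean_level annual mean concentration, ug/m3 (> 0).
#' @param seasonal_amplitude half-range of the seasonal cycle in the mean,
#'   ug/m3 (must be < `mean_level` so the mean stays positive).
#' @param peak_day day of year on which the seasonal mean peaks (default
#'   mid-July: warm-season secondary aerosol).
#' @param log_noise_sd standard deviation of multiplicative log-normal noise
#'   (on the log scale); 0 gives the seasonal mean exactly.
#' @param missing_rate fraction of days missing at random, in `[0, 1)`.
#' @param seed optional integer seed.
#' @return tibble with columns `monitor_id`, `latitude`, `longitude`,
#'   `date`, `pm25`; missing days are absent rows.
#' @export
generate_monitors <- function(monitors, start_date, end_date,
                              mean_level = 12, seasonal_amplitude = 3,
                              peak_day = 196, log_noise_sd = 0.4,
                              missing_rate = 0.1, seed = NULL) {
  monitors <- as.data.frame(monitors)
  stopifnot(all(c("monitor_id", "latitude", "longitude") %in% names(monitors)),
            nrow(monitors) >= 1)
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  if (is.na(start_date) || is.na(end_date) || start_date > end_date) {
    stop("invalid date range: start_date must be <= end_date", call. = FALSE)
  }
  if (mean_level <= 0) stop("mean_level must be positive", call. = FALSE)
  if (seasonal_amplitude < 0 || seasonal_amplitude >= mean_level) {
    stop("seasonal_amplitude must be in [0, mean_level)", call. = FALSE)
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)", call. = FALSE)
  }
  stopifnot(log_noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)

  dates <- seq(start_date, end_date, by = "day")
  n <- length(dates)
  mu <- mean_level +
    seasonal_amplitude * cos(2 * pi * (lubridate::yday(dates) - peak_day) / 365.25)

  out <- lapply(seq_len(nrow(monitors)), function(i) {
    pm <- mu * exp(stats::rnorm(n, 0, log_noise_sd))
    keep <- stats::runif(n) >= missing_rate
    tibble::tibble(
      monitor_id = monitors$monitor_id[i],
      latitude = monitors$latitude[i],
      longitude = monitors$longitude[i],
      date = dates[keep], pm25 = pm[keep]
    )
  })
  dplyr::bind_rows(out)
}
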