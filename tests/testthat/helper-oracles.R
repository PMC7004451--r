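# Independent oracles, deliberately naive, used to cross-check the package.

# Linear-interpolation percentile between order statistics at
# h = (n - 1) p + 1, written out by hand (no call to stats::quantile).
oracle_percentile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Exhaustive O(n^2) maximal-run finder over one contiguous day grid.
# `above` is logical with NA for missing days. A run [i, j] qualifies if
# every day is TRUE, it has length >= min_run, and it is not extendable.
oracle_runs <- function(above, min_run) {
  n <- length(above)
  ok <- function(i) isTRUE(above[i])
  out <- NULL
  for (i in seq_len(n)) for (j in i:n) {
    if (j - i + 1 < min_run) next
    if (all(vapply(i:j, ok, logical(1))) &&
        (i == 1 || !ok(i - 1)) && (j == n || !ok(j + 1))) {
      out <- rbind(out, c(start = i, end = j))
    }
  }
  out
}

# Small weather series for one station with controllable values.
toy_series <- function(tmax, start = "2000-06-01", station = "A") {
  tibble::tibble(station_id = station, latitude = 33, longitude = -90,
                 date = as.Date(start) + seq_along(tmax) - 1,
                 tmax = tmax, dew_point = tmax - 8)
}

# True models reused across tests: a null-interaction model and one with
# known joint ORs (1.5, 1.3, 2.3 -> RERI 0.5).
null_interaction_model <- function(prev = 0.08) {
  true_model(qlogis(prev), beta_pm = log(1.3), beta_ehe = log(1.2),
             beta_interaction = 0,
             covariate_betas = list(
               maternal_age_cat = c("<=19" = 0.10, ">=35" = 0.15),
               education_cat = c("<12y" = 0.10),
               race_ethnicity = c("NH-black" = 0.10, "Hispanic" = 0.05)),
             beta_dew_point = 0.01)
}

reri_half_model <- function(prev = 0.08) {
  true_model(qlogis(prev), beta_pm = log(1.5), beta_ehe = log(1.3),
             beta_interaction = log(2.3) - log(1.5) - log(1.3),
             covariate_betas = list(
               maternal_age_cat = c("<=19" = 0.10, ">=35" = 0.15),
               education_cat = c("<12y" = 0.10),
               race_ethnicity = c("NH-black" = 0.10, "Hispanic" = 0.05)),
             beta_dew_point = 0.01)
}
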