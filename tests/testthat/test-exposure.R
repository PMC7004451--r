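test_that("conception date and critical window are exact calendar arithmetic", {
  expect_equal(conception_date("2000-10-01"), as.Date("2000-01-09"))
  # independent check: 2001-03-01 minus 266 days computed by hand via
  # month lengths (Mar 1 2001 back 266: 59 days into 2001 + 207 into 2000)
  expect_equal(conception_date("2001-03-01"), as.Date("2000-06-08"))
  # shift equivariance
  expect_equal(conception_date("2000-10-02"), conception_date("2000-10-01") + 1)

  w <- critical_window(as.Date("2000-01-09")) # spans the leap day
  expect_equal(w$start, as.Date("2000-01-23"))
  expect_equal(w$end, as.Date("2000-03-04"))

  # window length always exactly 42 days; shift equivariance
  set.seed(1)
  conc <- as.Date("1995-01-01") + sample.int(8000, 50)
  ww <- critical_window(conc)
  expect_true(all(as.integer(ww$end - ww$start) + 1L == 42L))
  w7 <- critical_window(conc + 7)
  expect_equal(w7$start, ww$start + 7)
  expect_equal(w7$end, ww$end + 7)
})

test_that("alternate conception reconstruction from delivery date and gestational age", {
  # 40 menstrual weeks: conception two weeks after LMP
  expect_equal(conception_from_delivery("2000-10-01", 40),
               as.Date("2000-10-01") - 280 + 14)
})

test_that("haversine distance matches the spherical closed form", {
  expect_equal(haversine_km(33, -90, 33, -90), 0)
  expect_equal(haversine_km(0, 0, 1, 0), 6371 * pi / 180, tolerance = 1e-6)
  expect_equal(haversine_km(35.2, -101.4, 31.9, -87.2),
               haversine_km(31.9, -87.2, 35.2, -101.4))
  expect_error(haversine_km(95, 0, 0, 0), "out of range")
})

test_that("nearest-site linkage honors the distance cap and breaks ties by id", {
  sites <- data.frame(site_id = c("m3", "m1", "m2"),
                      latitude = c(33.05, 33.10, 33.20),
                      longitude = c(-90, -90, -90))
  hit <- nearest_site(33, -90, sites)
  expect_equal(hit$site_id, "m3")
  expect_equal(nearest_site(33.05, -90, sites)$distance_km, 0)

  # single monitor beyond the cap: subject excluded from PM analysis
  far <- data.frame(site_id = "m9", latitude = 33.54, longitude = -90)
  d <- haversine_km(33, -90, 33.54, -90)
  expect_gt(d, 50)
  expect_true(is.na(nearest_site(33, -90, far, max_km = 50)$site_id))
  expect_equal(nearest_site(33, -90, far)$site_id, "m9") # uncapped

  # exact tie broken by lexicographically smallest id
  tie <- data.frame(site_id = c("b", "a"), latitude = c(33.1, 32.9),
                    longitude = c(-90, -90))
  expect_equal(nearest_site(33, -90, tie)$site_id, "a")
  expect_error(nearest_site(33, -90, sites[0, ]), "empty site list")
})

test_that("window means respect the coverage rule and equal the brute-force mean", {
  d <- as.Date("2000-06-01") + 0:9
  wm <- window_mean(d[1:3], c(10, 20, 30), "2000-06-01", "2000-06-03",
                    min_days = 3)
  expect_equal(wm$mean, 20)
  expect_equal(wm$n_days, 3L)
  wm2 <- window_mean(d[1:2], c(10, 20), "2000-06-01", "2000-06-03",
                     min_days = 3)
  expect_true(is.na(wm2$mean))

  set.seed(2)
  for (k in 1:20) {
    dates <- as.Date("2000-01-01") + sort(sample.int(100, 40))
    vals <- rnorm(40, 12, 4)
    a <- as.Date("2000-01-01") + sample.int(60, 1)
    b <- a + 41
    inw <- dates >= a & dates <= b
    wm3 <- window_mean(dates, vals, a, b, min_days = 1)
    expect_equal(wm3$n_days, sum(inw))
    expect_equal(wm3$mean, sum(vals[inw]) / sum(inw))
  }
})

test_that("PM dichotomization uses the control percentile with strict exceedance", {
  ex <- tibble::tibble(mean_pm25 = c(1:100, 250, 260)) # last two are cases
  is_ctrl <- c(rep(TRUE, 100), FALSE, FALSE)
  out <- dichotomize_pm(ex, is_ctrl)
  expect_equal(attr(out, "pm_threshold"), 80.2)
  expect_equal(sum(out$pm_high[is_ctrl]), 20) # 81..100
  expect_true(all(out$pm_high[!is_ctrl]))

  # adding cases never moves the threshold (controls-only definition)
  ex2 <- tibble::tibble(mean_pm25 = c(1:100, runif(50, 0, 200)))
  out2 <- dichotomize_pm(ex2, c(rep(TRUE, 100), rep(FALSE, 50)))
  expect_equal(attr(out2, "pm_threshold"), attr(out, "pm_threshold"))

  # degenerate distribution: threshold c, ties classified low
  exc <- tibble::tibble(mean_pm25 = rep(7, 10))
  outc <- dichotomize_pm(exc, rep(TRUE, 10))
  expect_equal(attr(outc, "pm_threshold"), 7)
  expect_false(any(outc$pm_high))

  # large continuous sample: top 20% of controls flagged, within 1 subject
  set.seed(3)
  exl <- tibble::tibble(mean_pm25 = rlnorm(5000, log(12), 0.5))
  outl <- dichotomize_pm(exl, rep(TRUE, 5000))
  expect_lte(abs(sum(outl$pm_high) - 1000), 1)

  expect_error(dichotomize_pm(tibble::tibble(mean_pm25 = 1:5),
                              rep(FALSE, 5)), "controls")
})

test_that("seasons follow the MAM/JJA month convention", {
  expect_equal(season_of(as.Date("2000-06-15")), "summer")
  expect_equal(season_of(as.Date("2000-03-01")), "spring")
  expect_equal(season_of(as.Date("2000-12-31")), "winter")
  expect_equal(season_of(as.Date("2000-10-05")), "autumn")
  expect_equal(season_year(as.Date(c("2000-12-31", "2001-01-15"))),
               c(2001L, 2001L))
})

test_that("window season flags cover the three subpopulation definitions", {
  july <- season_flags(as.Date("2000-07-01"), as.Date("2000-08-11"))
  expect_true(july$any_day_spring_summer && july$entire_window_spring_summer &&
                july$any_day_summer)
  # winter-to-spring window: some spring days, none in summer
  wsp <- season_flags(as.Date("2000-02-15"), as.Date("2000-03-27"))
  expect_true(wsp$any_day_spring_summer)
  expect_false(wsp$entire_window_spring_summer)
  expect_false(wsp$any_day_summer)

  # implication: entire window in spring/summer => at least one day there
  set.seed(4)
  starts <- as.Date("1999-01-01") + sample.int(1000, 60)
  fl <- season_flags(starts, starts + 41)
  expect_true(all(!fl$entire_window_spring_summer | fl$any_day_spring_summer))
  expect_true(all(!fl$any_day_summer | fl$any_day_spring_summer))
})

test_that("exposure table flags linkage exclusions and is pure date arithmetic", {
  st <- data.frame(station_id = "W1", latitude = 33, longitude = -90)
  mo <- data.frame(monitor_id = "M1", latitude = 33, longitude = -90)
  w <- generate_weather(st, "1999-01-01", "2000-12-31", seed = 5)
  pm <- generate_monitors(mo, "1999-01-01", "2000-12-31", missing_rate = 0,
                          seed = 6)
  subj <- tibble::tibble(
    subject_id = c("a", "b"), is_case = c(TRUE, FALSE),
    outcome_group = c("VSDpm", "control"),
    latitude = c(33, 33.9), longitude = c(-90, -85), # b is ~460 km away
    edd = as.Date(c("2000-06-01", "2000-06-01")))
  ex <- build_exposure_table(subj, w, pm, dichotomize = "none")
  expect_equal(ex$monitor_id, c("M1", NA))
  expect_equal(ex$exclusion_reason, c(NA, "no_monitor_within_50km"))
  expect_equal(ex$n_pm_days[1], 42L)
  expect_false(is.na(ex$mean_dew_point[2])) # station linkage is uncapped
  expect_equal(ex$window_start, conception_date(subj$edd) + 14)
})
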