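test_that("weather generator reproduces the seasonal curve in the noise-free limit", {
  st <- data.frame(station_id = "A", latitude = 33, longitude = -90)
  w <- generate_weather(st, "2000-01-01", "2000-12-31",
                        base = 15, amplitude = 12, peak_day = 196,
                        ar1_rho = 0, noise_sd = 0, dewpoint_noise_sd = 0,
                        seed = 1)
  expect_equal(w$tmax, seasonal_tmax(w$date, 15, 12, 196))
  # sinusoid at its peak day: base + amplitude
  peak <- w$tmax[lubridate::yday(w$date) == 196]
  expect_equal(peak, 27)
  expect_equal(w$dew_point, w$tmax - 8)
  expect_equal(nrow(w), 366) # complete daily coverage, leap year
})

test_that("weather generator is deterministic under a fixed seed and validates inputs", {
  st <- data.frame(station_id = c("A", "B"), latitude = c(33, 34),
                   longitude = c(-90, -91))
  w1 <- generate_weather(st, "2000-01-01", "2001-12-31", seed = 42)
  w2 <- generate_weather(st, "2000-01-01", "2001-12-31", seed = 42)
  expect_identical(w1, w2)
  expect_error(generate_weather(st, "2001-01-01", "2000-01-01"), "date range")
  expect_error(generate_weather(st, "2000-01-01", "2000-12-31", ar1_rho = 1),
               "stationarity")
})

test_that("tmax anomalies have the requested lag-1 autocorrelation", {
  st <- data.frame(station_id = "A", latitude = 33, longitude = -90)
  for (rho in c(0.3, 0.7)) {
    w <- generate_weather(st, "1990-01-01", "2017-05-18", ar1_rho = rho,
                          noise_sd = 3, seed = 99) # 10,000 days
    a <- w$tmax - seasonal_tmax(w$date)
    r1 <- stats::cor(a[-1], a[-length(a)])
    expect_lt(abs(r1 - rho), 0.05)
  }
})

test_that("monitor generator honors its degenerate and missingness contracts", {
  mo <- data.frame(monitor_id = "M1", latitude = 33, longitude = -90)
  m0 <- generate_monitors(mo, "2000-01-01", "2000-12-31", mean_level = 12,
                          seasonal_amplitude = 0, log_noise_sd = 0,
                          missing_rate = 0, seed = 1)
  expect_true(all(m0$pm25 == 12))
  expect_equal(nrow(m0), 366) # missing_rate 0 -> complete coverage

  mh <- generate_monitors(mo, "2000-01-01", "2002-09-26", missing_rate = 0.5,
                          seed = 5) # 1000 days
  n_missing <- 1000 - nrow(mh)
  # binomial(1000, 0.5) central 99% bounds
  bounds <- qbinom(c(0.005, 0.995), 1000, 0.5)
  expect_gte(n_missing, bounds[1])
  expect_lte(n_missing, bounds[2])
  expect_error(generate_monitors(mo, "2000-01-01", "2000-12-31",
                                 mean_level = -1), "mean_level")
})

test_that("subject generator yields unique ids, honored marginals and season-spanning conceptions", {
  s <- generate_subjects(100, seed = 3)
  expect_equal(nrow(s), 100)
  expect_equal(anyDuplicated(s$subject_id), 0L)
  expect_true(all(s$gestational_age_weeks >= 20 & s$gestational_age_weeks <= 44))

  probs <- default_covariate_probs()
  probs$education_cat <- c("<12y" = 0, ">=12y" = 1)
  s2 <- generate_subjects(50, covariate_probs = probs, seed = 4)
  expect_true(all(s2$education_cat == ">=12y"))

  s3 <- generate_subjects(5000, edd_range = as.Date(c("2000-01-01",
                                                      "2002-12-31")),
                          seed = 6)
  conc_months <- sort(unique(lubridate::month(conception_date(s3$edd))))
  expect_equal(conc_months, 1:12)
  expect_error(generate_subjects(10, edd_range = c("2001-01-01", "2000-01-01")),
               "date interval")
})

test_that("outcome assignment matches its Bernoulli model", {
  n <- 50000
  s <- generate_subjects(n, seed = 10)
  expo <- tibble::tibble(subject_id = s$subject_id, pm_high = FALSE,
                         ehe95_exposed = FALSE, mean_dew_point = 10)
  m <- true_model(qlogis(0.2))
  out <- assign_outcomes(s, expo, m, seed = 11)
  se <- sqrt(0.2 * 0.8 / n)
  expect_lt(abs(mean(out$is_case) - 0.2), 3 * se)

  # intercept -> -inf limit: no cases
  out0 <- assign_outcomes(s, expo, true_model(-50), seed = 12)
  expect_equal(sum(out0$is_case), 0)

  # missing exposure record is an error
  expect_error(assign_outcomes(s, expo[-1, ], m), "missing exposure record")
})

test_that("case rate is independent of exposure category under the all-null model", {
  set.seed(13)
  n <- 40000
  s <- generate_subjects(n)
  expo <- tibble::tibble(subject_id = s$subject_id,
                         pm_high = runif(n) < 0.2,
                         ehe95_exposed = runif(n) < 0.35,
                         mean_dew_point = rnorm(n, 10, 4))
  out <- assign_outcomes(s, expo, true_model(qlogis(0.1)))
  joint <- interaction(expo$pm_high, expo$ehe95_exposed)
  p <- stats::chisq.test(table(joint, out$is_case))$p.value
  expect_gt(p, 0.01)
})

test_that("case-control sampling returns exact counts and preserves the odds ratio", {
  s <- generate_subjects(30000, seed = 20)
  set.seed(21)
  expo <- tibble::tibble(subject_id = s$subject_id,
                         pm_high = runif(30000) < 0.3,
                         ehe95_exposed = FALSE, mean_dew_point = 10)
  cohort <- assign_outcomes(s, expo, true_model(qlogis(0.15),
                                                beta_pm = log(2)))
  cc <- sample_case_control(cohort, 100, 200, seed = 22)
  expect_equal(sum(cc$is_case), 100)
  expect_equal(sum(!cc$is_case), 200)
  expect_error(sample_case_control(cohort, nrow(cohort), 10), "insufficient")

  # larger sample: case-control OR within the CI of the full-cohort OR
  cc2 <- sample_case_control(cohort, 1500, 1500, seed = 23)
  or_of <- function(d) {
    pm <- expo$pm_high[match(d$subject_id, expo$subject_id)]
    f <- glm(d$is_case ~ pm, family = binomial())
    c(coef(f)[["pmTRUE"]], sqrt(vcov(f)["pmTRUE", "pmTRUE"]))
  }
  full <- or_of(cohort)
  sub <- or_of(cc2)
  expect_lt(abs(sub[1] - full[1]), 1.96 * sqrt(full[2]^2 + sub[2]^2))
})

test_that("fitting recovers the generating log-odds ratios at nominal Wald coverage", {
  m <- null_interaction_model()
  set.seed(31)
  covered <- logical(100)
  for (r in seq_len(100)) {
    d <- simulate_cc_study(600, 600, m)
    des <- build_design(d, design_spec("VSDpm", "full", "EHE95"),
                        "product_term")
    fit <- fit_logistic(des$X, des$y)
    b <- fit$coefficients[["pm"]]
    se <- sqrt(fit$vcov["pm", "pm"])
    covered[r] <- abs(b - log(1.3)) < 1.96 * se
  }
  expect_gte(mean(covered), 0.90)
})
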