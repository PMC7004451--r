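# small helper: a modest case-control dataset with nonzero interaction
small_study <- function(seed = 101, n = 800) {
  simulate_cc_study(n, n, reri_half_model(), seed = seed)
}

test_that("design coding follows the reference conventions", {
  d <- small_study()
  spec <- design_spec("VSDpm", "full", "EHE95")
  des <- build_design(d, spec, "joint_4level")
  X <- des$X
  i10 <- d$pm_high & !d$ehe95_exposed
  # row order is preserved within build_design's filtering (no rows dropped)
  expect_equal(des$n_cases + des$n_controls, nrow(d))
  expect_equal(unname(X[, "joint10"]), as.numeric(i10))
  expect_equal(unname(X[, "joint11"]),
               as.numeric(d$pm_high & d$ehe95_exposed))
  # reference category: all three joint indicators zero
  ref <- !d$pm_high & !d$ehe95_exposed
  expect_true(all(X[ref, c("joint10", "joint01", "joint11")] == 0))

  desp <- build_design(d, spec, "product_term")
  Xp <- desp$X
  expect_equal(unname(Xp[, "pm:ehe"]), unname(Xp[, "pm"] * Xp[, "ehe"]))
  # full-population model carries the spring/summer indicator
  expect_true("spring_summer" %in% colnames(Xp))
  expect_false("spring_summer" %in%
                 colnames(build_design(d, design_spec("VSDpm",
                                                      "any_spring_summer",
                                                      "EHE95"),
                                       "product_term")$X))
})

test_that("logistic fit reproduces closed forms and an independent optimizer", {
  # intercept-only closed forms
  X <- matrix(1, 100, 1, dimnames = list(NULL, "(Intercept)"))
  f1 <- fit_logistic(X, rep(c(1, 0), each = 50))
  expect_equal(unname(f1$coefficients), 0, tolerance = 1e-8)
  f2 <- fit_logistic(X, rep(c(1, 0), c(20, 80)))
  expect_equal(unname(f2$coefficients), log(0.25), tolerance = 1e-8)
  expect_error(fit_logistic(X, rep(0, 100)), "at least 1 case")

  # against a direct Newton-free maximization of the same likelihood
  set.seed(40)
  n <- 400
  X3 <- cbind(`(Intercept)` = 1, x1 = rnorm(n), x2 = rbinom(n, 1, 0.4))
  y <- rbinom(n, 1, plogis(-0.5 + 0.8 * X3[, "x1"] - 0.4 * X3[, "x2"]))
  fit <- fit_logistic(X3, y)
  negll <- function(b) -sum(y * (X3 %*% b) - log1p(exp(X3 %*% b)))
  opt <- optim(c(0, 0, 0), negll, method = "BFGS",
               control = list(reltol = 1e-14))
  expect_equal(unname(fit$coefficients), opt$par, tolerance = 1e-4)
  expect_true(fit$converged)
  expect_true(isSymmetric(fit$vcov, tol = 1e-10))
  expect_true(all(eigen(fit$vcov, only.values = TRUE)$values > 0))
})

test_that("separation is detected and flagged", {
  X <- cbind(`(Intercept)` = 1, x = c(rep(0, 20), rep(1, 20)))
  y <- c(rep(0, 20), rep(1, 20))
  fit <- fit_logistic(X, y)
  expect_false(fit$converged)
  expect_error(stratum_ors(fit), "non-converged")
})

test_that("likelihood-ratio test matches the chi-square(1) tail", {
  f <- list(log_likelihood = -100, coefficients = 1:3)
  r <- list(log_likelihood = -100, coefficients = 1:2)
  out <- lrt_interaction(f, r)
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 1)
  # known tail points of chi-square(1)
  r2 <- list(log_likelihood = -100 - 2.706 / 2, coefficients = 1:2)
  expect_equal(lrt_interaction(f, r2)$p_value, 0.1, tolerance = 1e-3)
  r3 <- list(log_likelihood = -100 - 3.841 / 2, coefficients = 1:2)
  expect_equal(lrt_interaction(f, r3)$p_value, 0.05, tolerance = 1e-3)
  # negative statistic -> error
  rneg <- list(log_likelihood = -99, coefficients = 1:2)
  expect_error(lrt_interaction(f, rneg), "negative LRT")
  expect_error(lrt_interaction(f, f), "single product term")
})

test_that("stratum ORs equal a refit with the EHE stratum recoded", {
  d <- small_study(seed = 102)
  spec <- design_spec("VSDpm", "full", "EHE95")
  des <- build_design(d, spec, "product_term")
  fit <- fit_logistic(des$X, des$y)
  ors <- stratum_ors(fit, des$cols)
  expect_equal(ors$or_pm_ehe[["or"]],
               exp(fit$coefficients[["pm"]] + fit$coefficients[["pm:ehe"]]))

  # recode: ehe* = 1 - ehe makes the EHE stratum the reference, so the pm
  # main effect of the refit is the pm-within-EHE effect
  d2 <- d
  d2$ehe95_exposed <- !d2$ehe95_exposed
  des2 <- build_design(d2, spec, "product_term")
  fit2 <- fit_logistic(des2$X, des2$y)
  ors2 <- stratum_ors(fit2, des2$cols)
  expect_equal(ors$or_pm_ehe, ors2$or_pm_no_ehe, tolerance = 1e-6)
  expect_equal(ors$or_pm_no_ehe, ors2$or_pm_ehe, tolerance = 1e-6)
})

test_that("RERI point estimate is exact arithmetic on the stated formula", {
  expect_equal(reri_point(1, 1, 1), 0)
  expect_equal(reri_point(2.0, 1.5, 1.2), 0.3)
  expect_equal(reri_point(1.7, 1.4, 1.3), 0) # additive null
  # exchange of the two singly-exposed categories leaves RERI unchanged
  expect_equal(reri_point(2.3, 1.5, 1.3), reri_point(2.3, 1.3, 1.5))
  expect_error(reri_point(-1, 1, 1), "positive")
})

test_that("delta-method RERI interval collapses correctly and brackets the point", {
  d <- small_study(seed = 103)
  des <- build_design(d, design_spec("VSDpm", "full", "EHE95"),
                      "joint_4level")
  fit <- fit_logistic(des$X, des$y)
  dlt <- reri_ci_delta(fit)
  expect_lt(dlt$lower, dlt$estimate)
  expect_gt(dlt$upper, dlt$estimate)
  # degenerate covariance: interval collapses to the point
  fit0 <- fit
  fit0$vcov[, ] <- 0
  dlt0 <- reri_ci_delta(fit0)
  expect_equal(dlt0$lower, dlt0$estimate)
  expect_equal(dlt0$upper, dlt0$estimate)
})

test_that("profile-likelihood RERI interval satisfies its deviance definition", {
  d <- small_study(seed = 104)
  des <- build_design(d, design_spec("VSDpm", "full", "EHE95"),
                      "joint_4level")
  fit <- fit_logistic(des$X, des$y)
  prof <- reri_ci_profile(des$X, des$y, fit = fit)
  expect_equal(prof$status_lower, "ok")
  expect_equal(prof$status_upper, "ok")
  expect_lt(prof$lower, prof$estimate)
  expect_gt(prof$upper, prof$estimate)
  crit <- qchisq(0.95, 1)
  expect_lt(abs(prof$deviance_lower - crit), 1e-3)
  expect_lt(abs(prof$deviance_upper - crit), 1e-3)
  # the additive result wires the same interval through
  add <- additive_interaction(d, design_spec("VSDpm", "full", "EHE95"))
  expect_equal(add$reri,
               reri_point(add$or11[["or"]], add$or10[["or"]], add$or01[["or"]]))
})

test_that("profile and delta intervals agree asymptotically", {
  # one large cohort-style fit: at this n the two constructions should be
  # within 10% relative width of each other
  m <- reri_half_model(prev = 0.2)
  set.seed(105)
  big <- simulate_cc_study(20000, 20000, m, chunk_size = 120000)
  des <- build_design(big, design_spec("VSDpm", "full", "EHE95"),
                      "joint_4level")
  fit <- fit_logistic(des$X, des$y)
  dlt <- reri_ci_delta(fit)
  prof <- reri_ci_profile(des$X, des$y, fit = fit)
  w_d <- dlt$upper - dlt$lower
  w_p <- prof$upper - prof$lower
  expect_lt(abs(w_p - w_d) / w_d, 0.10)
  expect_lt(abs(prof$lower - dlt$lower), 0.1 * w_d)
})

test_that("the analysis grid has the right cardinality, nesting and determinism", {
  set.seed(106)
  n <- 1200
  base <- simulate_cc_study(n, n, reri_half_model())
  # give the tabular study genuine window dates so all filters are exercised
  conc <- as.Date("2000-01-01") + sample.int(1000, 2 * n, replace = TRUE)
  w <- critical_window(conc)
  fl <- season_flags(w$start, w$end)
  base$any_day_spring_summer <- fl$any_day_spring_summer
  base$entire_window_spring_summer <- fl$entire_window_spring_summer
  base$any_day_summer <- fl$any_day_summer
  base$outcome_group[base$is_case] <-
    sample(c("VSDpm", "RVOTO"), sum(base$is_case), replace = TRUE)

  res <- run_analysis(base, c("VSDpm", "RVOTO"),
                      profile_ci = FALSE)
  cells <- unique(res[, c("outcome_group", "population_filter",
                          "ehe_definition", "scale")])
  expect_equal(nrow(cells), 2 * 4 * 2 * 2) # 16 model cells x 2 scales
  expect_false(any(res$term == "error"))

  n_of <- function(f) {
    r <- res[res$population_filter == f & res$outcome_group == "VSDpm" &
               res$ehe_definition == "EHE95" & res$term == "reri", ]
    r$n_cases[1] + r$n_controls[1]
  }
  expect_lte(n_of("entire_spring_summer"), n_of("any_spring_summer"))
  expect_lte(n_of("any_spring_summer"), n_of("full"))

  res2 <- run_analysis(base, c("VSDpm", "RVOTO"), profile_ci = FALSE)
  expect_identical(res, res2)
})

test_that("complete-case exclusions are counted per model", {
  d <- small_study(seed = 107, n = 300)
  d$mean_dew_point[1:10] <- NA
  des <- build_design(d, design_spec("VSDpm", "full", "EHE95"),
                      "product_term")
  expect_equal(des$n_dropped, 10)
  expect_equal(des$n_cases + des$n_controls, nrow(d) - 10)
})
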